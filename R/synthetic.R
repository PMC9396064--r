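#' Stopped-flow instrument model
#'
#' Captures the instrument effects the generators emulate: the dead time
#' between mixing and the first observable point (points earlier than it are
#' truncated, not shifted; t = 0 is flow stop), additive Gaussian absorbance
#' noise, log-spaced sampling mirroring the logarithmic time axes of
#' transient data, and the hard 1.5 AU CCD saturation limit.
#'
#' @param dead_time Instrument dead time, s.
#' @param noise_sd Absorbance noise standard deviation, AU.
#' @param n_points Number of log-spaced samples per trace (>= 50).
#' @param span Trace duration, s, or `NULL` to auto-scale each trace to
#'   about six time constants of its slowest expected phase.
#' @param seed Root seed; every trace derives its own substream from it.
#' @return An `instrument_model` object.
#' @export
instrument_model <- function(dead_time = 0.0015, noise_sd = 0.002,
                             n_points = 400, span = NULL, seed = 1L) {
  stopifnot(dead_time >= 0, noise_sd >= 0, n_points >= 50)
  structure(list(dead_time = dead_time, noise_sd = noise_sd,
                 n_points = as.integer(n_points), span = span,
                 saturation_limit = 1.5, seed = as.integer(seed)),
            class = "instrument_model")
}

#' Derive a reproducible substream seed from a root seed and a label
#'
#' All randomness in the generators flows from one root seed through named
#' substreams, so identical seeds give bit-identical datasets while distinct
#' traces get independent noise.
#'
#' @param seed Integer root seed.
#' @param label Character substream label.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

log_grid <- function(instrument, span) {
  t0 <- max(instrument$dead_time, span * 1e-4)
  exp(seq(log(t0), log(span), length.out = instrument$n_points))
}

finish_trace <- function(series, wavelength, instrument, label, meta) {
  tr <- project_absorbance(series, extinction_table(), wavelength,
                           metadata = meta)
  tr$metadata$dead_time <- instrument$dead_time
  tr$metadata$noise_sd <- instrument$noise_sd
  tr$metadata$seed <- derive_seed(instrument$seed, label)
  if (instrument$noise_sd > 0) {
    tr$absorbance <- tr$absorbance + with_seed(
      tr$metadata$seed, stats::rnorm(length(tr$time), 0, instrument$noise_sd))
  }
  tr
}

#' Generate synthetic reductive half-reaction traces (450 nm)
#'
#' Simulates mixing oxidized enzyme against excess pseudooxynicotine and
#' watching flavin reduction at 450 nm. Noiseless traces are biexponential:
#' a fast hyperbolically concentration-dependent hydride-transfer phase and
#' a concentration-invariant product-release phase.
#'
#' @param params A [pnao_params()] object.
#' @param pon_concs Pon concentrations after mixing, mol/L (0 < c <= 1e-3).
#'   The default panel mirrors a 0.05-1 mM before-mixing series.
#' @param instrument An [instrument_model()].
#' @param enzyme_conc Enzyme concentration after mixing, mol/L.
#' @return List of `sf_trace` objects, one per concentration.
#' @export
generate_reductive <- function(params,
                               pon_concs = c(25, 50, 100, 150, 250, 375, 500) * 1e-6,
                               instrument = instrument_model(),
                               enzyme_conc = 17.5e-6) {
  validate_pnao_params(params)
  if (!length(pon_concs)) stop("empty Pon concentration list", call. = FALSE)
  if (any(pon_concs <= 0) || any(pon_concs > 1e-3)) {
    stop("Pon concentrations must lie in (0, 1e-3] mol/L after mixing",
         call. = FALSE)
  }
  scheme <- build_pnao_scheme(params, "reductive")
  lapply(seq_along(pon_concs), function(i) {
    s <- pon_concs[i]
    keff <- params$k_red * s / (params$Kd_pon + s)
    span <- instrument$span
    if (is.null(span)) span <- 6 / min(keff, params$k_rel)
    tg <- log_grid(instrument, span)
    series <- integrate_scheme(scheme,
                               c(E_ox = enzyme_conc, Pon = s), tg)
    finish_trace(series, 450, instrument, sprintf("reductive_%d", i),
                 meta = list(experiment = "reductive", pon_conc = s,
                             enzyme_conc = enzyme_conc,
                             temperature = params$temperature))
  })
}

#' Generate synthetic O2 reoxidation traces (450 nm)
#'
#' Reduced enzyme mixed against O2-equilibrated buffer; flavin reoxidation
#' is a single slow pseudo-first-order phase with rate k_ox_o2 * \[O2\]
#' (the semiquinone, once formed, is essentially O2-inert, so no
#' intermediate phase appears).
#'
#' @inheritParams generate_reductive
#' @param o2_concs O2 concentrations after mixing, mol/L (0 < c <= 1.3e-3,
#'   air-saturated to pure O2).
#' @return List of `sf_trace` objects.
#' @export
generate_oxidation_o2 <- function(params,
                                  o2_concs = c(75, 150, 300, 600, 1200) * 1e-6,
                                  instrument = instrument_model(),
                                  enzyme_conc = 17.5e-6) {
  validate_pnao_params(params)
  if (!length(o2_concs)) stop("empty O2 concentration list", call. = FALSE)
  if (any(o2_concs <= 0) || any(o2_concs > 1.3e-3)) {
    stop("O2 concentrations must lie in (0, 1.3e-3] mol/L", call. = FALSE)
  }
  scheme <- build_pnao_scheme(params, "oxidation_o2")
  lapply(seq_along(o2_concs), function(i) {
    ox <- o2_concs[i]
    span <- instrument$span
    if (is.null(span)) span <- 6 / (params$k_ox_o2 * ox)
    tg <- log_grid(instrument, span)
    series <- integrate_scheme(scheme, c(E_red = enzyme_conc, O2 = ox), tg)
    finish_trace(series, 450, instrument, sprintf("oxidation_o2_%d", i),
                 meta = list(experiment = "oxidation_o2", o2_conc = ox,
                             enzyme_conc = enzyme_conc,
                             temperature = params$temperature))
  })
}

#' Generate synthetic CycN reoxidation traces (550 nm)
#'
#' Reduced enzyme mixed against excess oxidized CycN; the 550 nm rise
#' reports CycN reduction through two sequential one-electron transfers
#' (hydroquinone -> semiquinone -> oxidized), plus a minor additive
#' empirical phase of rate `k_art` and amplitude `frac_art` of the main
#' amplitude (its origin is unresolved, so it is not given a mechanistic
#' species). CycN is held fixed during generation (excess-oxidant,
#' pseudo-first-order regime), which the precondition
#' `cycn_concs >= 2 * enzyme_conc` enforces.
#'
#' @inheritParams generate_reductive
#' @param cycn_concs Oxidized CycN concentrations after mixing, mol/L.
#' @param enzyme_conc Reduced enzyme after mixing, mol/L.
#' @return List of `sf_trace` objects.
#' @export
generate_oxidation_cycn <- function(params,
                                    cycn_concs = c(10, 20, 40, 80, 160, 320) * 1e-6,
                                    instrument = instrument_model(),
                                    enzyme_conc = 5e-6) {
  validate_pnao_params(params)
  if (!length(cycn_concs)) stop("empty CycN concentration list", call. = FALSE)
  if (any(cycn_concs < 2 * enzyme_conc * (1 - 1e-9))) {
    stop("cycn_concs must be >= 2 * enzyme_conc (excess-oxidant regime); ",
         "sub-stoichiometric mixes are unsupported", call. = FALSE)
  }
  scheme <- build_pnao_scheme(params, "oxidation_cycn")
  lapply(seq_along(cycn_concs), function(i) {
    cc <- cycn_concs[i]
    span <- instrument$span
    if (is.null(span)) {
      slow <- min(params$k_cyc2 * cc,
                  if (params$frac_art > 0) params$k_art else Inf)
      span <- 6 / slow
    }
    tg <- log_grid(instrument, span)
    series <- integrate_scheme(scheme,
                               c(E_red = enzyme_conc, CycN_ox = cc), tg)
    tr <- project_absorbance(series, extinction_table(), 550,
                             metadata = list(experiment = "oxidation_cycn",
                                             cycn_conc = cc,
                                             enzyme_conc = enzyme_conc,
                                             temperature = params$temperature))
    if (params$frac_art > 0) {
      main_amp <- 21000 * 2 * enzyme_conc  # full two-electron 550 nm rise
      art_amp <- params$frac_art * main_amp
      tr$absorbance <- tr$absorbance +
        art_amp * (1 - exp(-params$k_art * tr$time))
      tr$saturated <- tr$absorbance > 1.5
    }
    tr$metadata$dead_time <- instrument$dead_time
    tr$metadata$noise_sd <- instrument$noise_sd
    tr$metadata$seed <- derive_seed(instrument$seed,
                                    sprintf("oxidation_cycn_%d", i))
    if (instrument$noise_sd > 0) {
      tr$absorbance <- tr$absorbance + with_seed(
        tr$metadata$seed,
        stats::rnorm(length(tr$time), 0, instrument$noise_sd))
    }
    tr
  })
}

#' Generate a synthetic steady-state initial-velocity dataset
#'
#' Turnover of CycN reduction at saturating Pon, reported as per-enzyme
#' velocities already divided by two (two CycN molecules are reduced per
#' catalytic cycle).
#'
#' Two modes: `empirical` draws velocities from the Michaelis-Menten law at
#' the empirical `kcat_emp`/`Km_cyc_emp` with multiplicative Gaussian noise;
#' `mechanistic` integrates full-cycle progress curves at each CycN
#' concentration and extracts initial velocities with [extract_velocity()]
#' (noiseless; it exposes the cycle flux implied by the microscopic
#' constants, which predicts a much larger Km than measured).
#'
#' @param params A [pnao_params()] object.
#' @param cycn_concs CycN concentrations after mixing, mol/L (default panel
#'   2.5-80 uM, i.e. 5-160 uM before mixing).
#' @param mode `"empirical"` or `"mechanistic"`.
#' @param replicates Replicates per concentration (empirical mode).
#' @param seed Integer seed.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param enzyme_conc,pon_conc Enzyme and Pon after mixing, mol/L.
#' @return A `steady_state_dataset`: data frame with columns `cycn_conc`,
#'   `velocity`, `replicate`, plus attributes.
#' @export
generate_steady_state <- function(params,
                                  cycn_concs = c(2.5, 5, 10, 20, 30, 40, 60, 80) * 1e-6,
                                  mode = c("empirical", "mechanistic"),
                                  replicates = 3L, seed = 1L, cv = 0.05,
                                  enzyme_conc = 1e-7, pon_conc = 1e-3) {
  validate_pnao_params(params)
  mode <- match.arg(mode)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (any(cycn_concs <= 0) || anyDuplicated(cycn_concs)) {
    stop("cycn_concs must be strictly positive and distinct", call. = FALSE)
  }
  if (mode == "empirical") {
    v_true <- params$kcat_emp * cycn_concs /
      (params$Km_cyc_emp + cycn_concs)
    df <- expand.grid(replicate = seq_len(replicates),
                      cycn_conc = cycn_concs)[, 2:1]
    noise <- if (cv > 0) {
      with_seed(derive_seed(seed, "steady_state_empirical"),
                stats::rnorm(nrow(df), 0, cv))
    } else numeric(nrow(df))
    df$velocity <- pmax(0, rep(v_true, each = replicates) * (1 + noise))
  } else {
    scheme <- build_pnao_scheme(params, "full_cycle")
    keff <- params$k_red * pon_conc / (params$Kd_pon + pon_conc)
    v <- vapply(cycn_concs, function(cc) {
      # closed-form cycle flux only to size the window; velocity itself
      # comes from the integrated progress curve
      v_pred <- 1 / (1 / keff + 1 / params$k_rel +
                     1 / (params$k_cyc1 * cc) + 1 / (params$k_cyc2 * cc))
      t_end <- 0.15 * cc / (2 * v_pred * enzyme_conc)
      tg <- seq(t_end / 200, t_end, length.out = 200)
      series <- integrate_scheme(scheme,
                                 c(E_ox = enzyme_conc, Pon = pon_conc,
                                   CycN_ox = cc), tg)
      tr <- project_absorbance(series, extinction_table(), 550,
                               metadata = list(experiment = "steady_state",
                                               cycn_conc = cc,
                                               enzyme_conc = enzyme_conc))
      # a tight 2% amplitude window keeps the secant slope within ~1% of
      # the instantaneous initial rate despite oxidant depletion
      extract_velocity(tr, enzyme_conc, window_fraction = 0.02)
    }, numeric(1))
    df <- data.frame(cycn_conc = cycn_concs, velocity = v, replicate = 1L)
  }
  structure(df, class = c("steady_state_dataset", "data.frame"),
            mode = mode, enzyme_conc = enzyme_conc, pon_conc = pon_conc,
            replicates = as.integer(replicates), seed = as.integer(seed))
}

#' Generate a synthetic reductive redox titration
#'
#' Emulates the Massey xanthine/xanthine-oxidase method: electrons are
#' delivered slowly and monotonically into an anaerobic cuvette holding the
#' enzyme couple and an indicator dye, and at every step the two couples are
#' at mutual Nernst equilibrium. The xanthine-oxidase/mediator chemistry is
#' abstracted to the monotone delivery schedule itself; its only role in the
#' method is slow equilibration.
#'
#' @param params A [pnao_params()] object (uses `Em_enz`, `n_enz`, `Em_dye`,
#'   `n_dye`).
#' @param steps Number of titration steps (>= 10); delivered electrons run
#'   linearly from zero to the full capacity of both couples.
#' @param noise_sd Gaussian absorbance noise, AU, applied to the enzyme-band
#'   and dye-band absorbances.
#' @param seed Integer seed.
#' @param enzyme_conc,dye_conc Couple totals, mol/L. Defaults correspond to
#'   starting absorbances of ~0.4 AU for each band.
#' @param temperature Temperature, K.
#' @return A `titration_series`: data frame with columns `step`,
#'   `delivered`, `potential_mV`, `f_enz`, `f_dye`, `A_enz`, `A_dye`, plus
#'   attributes holding the totals and couple parameters.
#' @export
generate_titration <- function(params, steps = 40L, noise_sd = 0,
                               seed = 1L,
                               enzyme_conc = 0.4 / 11300,
                               dye_conc = 0.4 / 20200,
                               temperature = 298.15) {
  validate_pnao_params(params)
  if (steps < 10) stop("steps must be >= 10", call. = FALSE)
  capacity <- params$n_enz * enzyme_conc + params$n_dye * dye_conc
  delivered <- seq(0, capacity, length.out = steps)
  eq <- lapply(delivered, function(d)
    equilibrium_partition(d, params, enzyme_conc, dye_conc, temperature))
  f_enz <- vapply(eq, `[[`, numeric(1), "f_enz")
  f_dye <- vapply(eq, `[[`, numeric(1), "f_dye")
  pot <- vapply(eq, `[[`, numeric(1), "potential_mV")
  # isolated enzyme flavin band (ox -> anionic semiquinone) and dye 600 nm
  # band (oxidized dye colored, reduced colorless)
  A_enz <- enzyme_conc * ((1 - f_enz) * 11300 + f_enz * 4000)
  A_dye <- dye_conc * (1 - f_dye) * 20200
  if (noise_sd > 0) {
    nz <- with_seed(derive_seed(seed, "titration"),
                    stats::rnorm(2 * steps, 0, noise_sd))
    A_enz <- A_enz + nz[seq_len(steps)]
    A_dye <- A_dye + nz[steps + seq_len(steps)]
  }
  in_window <- f_enz > 0.1 & f_enz < 0.9 & f_dye > 0.1 & f_dye < 0.9
  if (sum(in_window) < 5) {
    warning("fewer than 5 steps bracket both midpoints; increase steps",
            call. = FALSE)
  }
  structure(data.frame(step = seq_len(steps), delivered = delivered,
                       potential_mV = pot, f_enz = f_enz, f_dye = f_dye,
                       A_enz = A_enz, A_dye = A_dye),
            class = c("titration_series", "data.frame"),
            enzyme_conc = enzyme_conc, dye_conc = dye_conc,
            Em_dye = params$Em_dye, n_dye = params$n_dye,
            n_enz = params$n_enz, temperature = temperature,
            noise_sd = noise_sd, seed = as.integer(seed))
}
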