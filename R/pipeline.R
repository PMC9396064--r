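#' Single-seed per-experiment recovery analyses
#'
#' Each function generates one synthetic dataset for its experiment class at
#' the given seed and runs the corresponding fitting chain, returning the
#' recovered constants. They are the building blocks of [run_recovery()] and
#' of multi-seed recovery studies.
#'
#' @param params Generating [pnao_params()].
#' @param seed Integer seed for the instrument noise substreams.
#' @param noise_sd Absorbance noise, AU.
#' @param n_points Points per trace.
#' @return A named list of recovered values (see each function's fields).
#' @name recovery-steps
NULL

#' @describeIn recovery-steps Biexponential fits of the 450 nm reductive
#'   traces; hyperbolic secondary fit of the fast phase (`k_red`, `Kd_pon`)
#'   and inverse-variance constant fit of the slow phase (`k_rel`). Also
#'   returns `converged`.
#' @export
recover_reductive <- function(params, seed = 1L, noise_sd = 0.002,
                              n_points = 400L) {
  inst <- instrument_model(noise_sd = noise_sd, n_points = n_points,
                           seed = seed)
  traces <- generate_reductive(params, instrument = inst)
  fits <- lapply(traces, fit_exponentials, phases = 2)
  conc <- vapply(traces, function(tr) tr$metadata$pon_conc, numeric(1))
  p1 <- data.frame(conc = conc,
                   k_obs = vapply(fits, function(f) f$rates[1], numeric(1)),
                   se = vapply(fits, function(f) f$rate_se[1], numeric(1)))
  p2 <- data.frame(conc = conc,
                   k_obs = vapply(fits, function(f) f$rates[2], numeric(1)),
                   se = vapply(fits, function(f) f$rate_se[2], numeric(1)))
  hyp <- fit_secondary(p1, "hyperbolic")
  const <- fit_secondary(p2, "constant")
  list(k_red = hyp$k_red, Kd_pon = hyp$Kd, k_rel = const$mean,
       converged = all(vapply(fits, `[[`, logical(1), "converged")))
}

#' @describeIn recovery-steps Single-exponential fits of the 450 nm O2
#'   reoxidation traces and a linear secondary fit; returns the slope
#'   `k_ox_o2` (1/(M s)), `intercept` and `converged`.
#' @export
recover_oxidation_o2 <- function(params, seed = 1L, noise_sd = 0.002,
                                 n_points = 400L) {
  inst <- instrument_model(noise_sd = noise_sd, n_points = n_points,
                           seed = seed)
  traces <- generate_oxidation_o2(params, instrument = inst)
  fits <- lapply(traces, fit_exponentials, phases = 1)
  lin <- fit_secondary(data.frame(
    conc = vapply(traces, function(tr) tr$metadata$o2_conc, numeric(1)),
    k_obs = vapply(fits, function(f) f$rates[1], numeric(1)),
    se = vapply(fits, function(f) f$rate_se[1], numeric(1))), "linear")
  list(k_ox_o2 = lin$slope, intercept = lin$intercept,
       converged = all(vapply(fits, `[[`, logical(1), "converged")))
}

#' @describeIn recovery-steps Three-exponential fits of the 550 nm CycN
#'   traces; phases labeled by [assign_cycn_phases()]; linear secondary fits
#'   of the two major phases (`k_cyc1`, `k_cyc2`) and an inverse-variance
#'   constant fit of the minor phase (`k_art`).
#' @export
recover_oxidation_cycn <- function(params, seed = 1L, noise_sd = 0.002,
                                   n_points = 400L) {
  inst <- instrument_model(noise_sd = noise_sd, n_points = n_points,
                           seed = seed)
  traces <- generate_oxidation_cycn(params, instrument = inst)
  fits <- lapply(traces, fit_exponentials, phases = 3)
  conc <- vapply(traces, function(tr) tr$metadata$cycn_conc, numeric(1))
  lab <- lapply(fits, assign_cycn_phases)
  mk <- function(field) data.frame(
    conc = conc,
    k_obs = vapply(lab, `[[`, numeric(1), field),
    se = vapply(lab, `[[`, numeric(1), paste0(field, "_se")))
  minor <- mk("k_minor")
  # keep only traces whose minor phase is resolved with a usable variance
  minor <- minor[is.finite(minor$k_obs) & is.finite(minor$se) & minor$se > 0, ]
  k_art <- if (length(unique(minor$conc)) >= 3) {
    fit_secondary(minor, "constant")$mean
  } else if (nrow(minor)) {
    # too few traces resolve the minor phase for a formal constant fit
    stats::weighted.mean(minor$k_obs, 1 / minor$se^2)
  } else NA_real_
  list(k_cyc1 = fit_secondary(mk("k1"), "linear")$slope,
       k_cyc2 = fit_secondary(mk("k2"), "linear")$slope,
       k_art = k_art,
       converged = all(vapply(fits, `[[`, logical(1), "converged")))
}

#' @describeIn recovery-steps Empirical-mode steady-state dataset plus
#'   Michaelis-Menten fit; returns `kcat`, `Km` and the `mm_fit` object.
#' @export
recover_steady_state <- function(params, seed = 1L) {
  mm <- fit_mm(generate_steady_state(params, seed = seed))
  list(kcat = mm$kcat, Km = mm$Km, fit = mm)
}

#' End-to-end parameter-recovery run
#'
#' Generates all four experiment classes from one seeded parameter set, runs
#' the full fitting chain (per-trace exponential fits, secondary analyses,
#' Michaelis-Menten fit, Nernst analysis, consistency analysis) and reports
#' recovered versus generating parameters: hydride transfer and product
#' release from the reductive traces, the O2 and CycN bimolecular constants
#' from the oxidative traces, the empirical steady-state parameters, and
#' the flavin midpoint potential from the titration.
#'
#' @param params Generating [pnao_params()].
#' @param seed Root seed; each experiment derives a named substream.
#' @param noise_sd Stopped-flow absorbance noise, AU.
#' @param titration_noise_sd Titration absorbance noise, AU.
#' @param n_points Points per stopped-flow trace.
#' @return A `recovery_report`: list with `recovered`, `generating`,
#'   `relative_error` (named vectors over k_red, Kd_pon, k_rel, k_ox_o2,
#'   k_cyc1, k_cyc2, k_art, kcat, Km, Em_enz), the `consistency` report and
#'   `all_converged`.
#' @examples
#' \donttest{
#' rep1 <- run_recovery(pnao_params(), seed = 1)
#' rep1$relative_error
#' }
#' @export
run_recovery <- function(params = pnao_params(), seed = 1L,
                         noise_sd = 0.002, titration_noise_sd = 0,
                         n_points = 400L) {
  red <- recover_reductive(params, derive_seed(seed, "reductive"),
                           noise_sd, n_points)
  o2 <- recover_oxidation_o2(params, derive_seed(seed, "oxidation_o2"),
                             noise_sd, n_points)
  cyc <- recover_oxidation_cycn(params, derive_seed(seed, "oxidation_cycn"),
                                noise_sd, n_points)
  ss <- recover_steady_state(params, derive_seed(seed, "steady"))
  consistency <- consistency_analysis(ss$fit, params)
  tit <- generate_titration(params, steps = 40,
                            noise_sd = titration_noise_sd,
                            seed = derive_seed(seed, "titration"))
  nf <- nernst_fit(tit)

  recovered <- c(k_red = red$k_red, Kd_pon = red$Kd_pon, k_rel = red$k_rel,
                 k_ox_o2 = o2$k_ox_o2, k_cyc1 = cyc$k_cyc1,
                 k_cyc2 = cyc$k_cyc2, k_art = cyc$k_art,
                 kcat = ss$kcat, Km = ss$Km, Em_enz = nf$Em_enz_mV)
  generating <- c(k_red = params$k_red, Kd_pon = params$Kd_pon,
                  k_rel = params$k_rel, k_ox_o2 = params$k_ox_o2,
                  k_cyc1 = params$k_cyc1, k_cyc2 = params$k_cyc2,
                  k_art = params$k_art, kcat = params$kcat_emp,
                  Km = params$Km_cyc_emp, Em_enz = params$Em_enz)
  structure(list(seed = as.integer(seed),
                 recovered = recovered, generating = generating,
                 relative_error = (recovered - generating) / abs(generating),
                 consistency = consistency,
                 all_converged = red$converged && o2$converged &&
                   cyc$converged),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter-recovery report (seed", x$seed, ")\n")
  tab <- data.frame(generating = signif(x$generating, 4),
                    recovered = signif(x$recovered, 4),
                    rel_error = signif(x$relative_error, 3))
  print(tab)
  cat("all fits converged:", x$all_converged, "\n")
  print(x$consistency)
  invisible(x)
}

#' Serialize a recovery report to JSON
#'
#' @param report A `recovery_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_recovery_report <- function(report, path) {
  stopifnot(inherits(report, "recovery_report"))
  payload <- list(seed = report$seed,
                  recovered = as.list(report$recovered),
                  generating = as.list(report$generating),
                  relative_error = as.list(report$relative_error),
                  consistency = unclass(report$consistency),
                  all_converged = report$all_converged)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
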