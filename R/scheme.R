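#' Construct a kinetic reaction scheme
#'
#' A scheme is a set of species plus reactions in which exactly one
#' enzyme-state reactant is converted to exactly one enzyme-state product
#' (so total enzyme-bound flavin is conserved by construction). Reactions
#' carry one of three rate laws:
#' \describe{
#'   \item{first}{flux = k * \[from\]}
#'   \item{bimolecular}{flux = k * \[from\] * \[partner\]}
#'   \item{saturating}{flux = k * \[sub\]/(Kd + \[sub\]) * \[from\] —
#'     rapid-equilibrium lumping of substrate binding}
#' }
#' Species named in `excess` are held at their initial concentration during
#' integration (pseudo-first-order approximation).
#'
#' @param species Character vector of all species identifiers.
#' @param reactions List of reactions from [reaction_step()].
#' @param enzyme_states Character vector naming the species that are enzyme
#'   flavin states (the conserved group).
#' @param excess Character vector of species treated as in excess.
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(species, reactions, enzyme_states,
                           excess = character()) {
  stopifnot(is.character(species), length(species) > 0,
            is.list(reactions), is.character(enzyme_states))
  if (!all(enzyme_states %in% species)) {
    stop("enzyme_states must be a subset of species", call. = FALSE)
  }
  if (!all(excess %in% species)) {
    stop("excess species must be a subset of species", call. = FALSE)
  }
  for (r in reactions) {
    stopifnot(inherits(r, "reaction_step"))
    if (!(r$from %in% enzyme_states) || !(r$to %in% enzyme_states)) {
      stop("each reaction must map one enzyme state to one enzyme state",
           call. = FALSE)
    }
    others <- c(r$partner, r$sub, r$produced)
    others <- others[!is.na(others) & nzchar(others)]
    if (!all(others %in% species)) {
      stop("reaction references unknown species: ",
           paste(setdiff(others, species), collapse = ", "), call. = FALSE)
    }
    if (r$type == "bimolecular" && (is.na(r$partner) || !nzchar(r$partner))) {
      stop("bimolecular reaction needs exactly two reactants (a partner)",
           call. = FALSE)
    }
  }
  structure(list(species = species, reactions = reactions,
                 enzyme_states = enzyme_states, excess = excess),
            class = "kinetic_scheme")
}

#' Define one reaction of a kinetic scheme
#'
#' @param from,to Enzyme-state reactant and product.
#' @param k Rate constant (1/s for first order and saturating; 1/(M s) for
#'   bimolecular).
#' @param type Rate law, one of `"first"`, `"bimolecular"`, `"saturating"`.
#' @param partner Second reactant of a bimolecular step (consumed).
#' @param produced Optional non-enzyme species produced by the step.
#' @param sub,Kd Substrate species and apparent dissociation constant of a
#'   saturating step.
#' @return An object of class `reaction_step`.
#' @export
reaction_step <- function(from, to, k,
                          type = c("first", "bimolecular", "saturating"),
                          partner = NA_character_,
                          produced = character(),
                          sub = NA_character_, Kd = NA_real_) {
  type <- match.arg(type)
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k >= 0)
  if (type == "saturating" && (is.na(sub) || !is.finite(Kd) || Kd <= 0)) {
    stop("saturating step needs a substrate species and Kd > 0", call. = FALSE)
  }
  structure(list(from = from, to = to, k = k, type = type, partner = partner,
                 produced = produced, sub = sub, Kd = Kd),
            class = "reaction_step")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme:", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  for (r in x$reactions) {
    lhs <- r$from
    if (r$type == "bimolecular") lhs <- paste(lhs, "+", r$partner)
    rhs <- paste(c(r$to, r$produced), collapse = " + ")
    law <- switch(r$type,
                  first = sprintf("k = %.4g 1/s", r$k),
                  bimolecular = sprintf("k = %.4g 1/(M s)", r$k),
                  saturating = sprintf("k = %.4g 1/s, Kd(%s) = %.4g M",
                                       r$k, r$sub, r$Kd))
    cat(sprintf("  %s -> %s   [%s]\n", lhs, rhs, law))
  }
  if (length(x$excess)) cat("  excess:", paste(x$excess, collapse = ", "), "\n")
  invisible(x)
}

#' Build the Pnao catalytic-cycle scheme for one experiment class
#'
#' Encodes the proposed cycle: Pon reduces the flavin in a rapid-equilibrium
#' binding step followed by hydride transfer (lumped to an effective rate
#' k_red\[S\]/(Kd+\[S\])), the imine product dissociates, and the free
#' reduced enzyme is reoxidized either slowly by O2 (single two-electron
#' step; the semiquinone is essentially unreactive toward O2) or rapidly by
#' two sequential one-electron transfers to oxidized CycN through an
#' obligate anionic semiquinone intermediate. All steps are treated as
#' irreversible over the observed windows.
#'
#' @param params A [pnao_params()] object.
#' @param experiment One of `"reductive"`, `"oxidation_o2"`,
#'   `"oxidation_cycn"`, `"full_cycle"`.
#' @param explicit_binding If `TRUE`, the reductive substrate-binding step is
#'   modeled explicitly with `k_on = 1e7` 1/(M s) and `k_off = k_on * Kd_pon`
#'   instead of the rapid-equilibrium lumping (sensitivity checks only).
#' @return A [kinetic_scheme()].
#' @examples
#' sc <- build_pnao_scheme(pnao_params(), "oxidation_cycn")
#' eigenrates(sc, c(CycN_ox = 50e-6))
#' @export
build_pnao_scheme <- function(params,
                              experiment = c("reductive", "oxidation_o2",
                                             "oxidation_cycn", "full_cycle"),
                              explicit_binding = FALSE) {
  validate_pnao_params(params)
  if (length(experiment) != 1L || !experiment %in%
      c("reductive", "oxidation_o2", "oxidation_cycn", "full_cycle")) {
    stop("unknown experiment tag: ",
         paste(experiment, collapse = ", "),
         " (expected reductive, oxidation_o2, oxidation_cycn or full_cycle)",
         call. = FALSE)
  }

  red_steps <- function() {
    if (explicit_binding) {
      k_on <- 1e7
      list(
        reaction_step("E_ox", "E_ox_S", k_on, "bimolecular", partner = "Pon"),
        reaction_step("E_ox_S", "E_ox", k_on * params$Kd_pon, "first",
                      produced = "Pon"),
        reaction_step("E_ox_S", "E_red_P", params$k_red, "first"),
        reaction_step("E_red_P", "E_red", params$k_rel, "first",
                      produced = "P")
      )
    } else {
      list(
        reaction_step("E_ox", "E_red_P", params$k_red, "saturating",
                      sub = "Pon", Kd = params$Kd_pon),
        reaction_step("E_red_P", "E_red", params$k_rel, "first",
                      produced = "P")
      )
    }
  }
  cyc_steps <- list(
    reaction_step("E_red", "E_sq", params$k_cyc1, "bimolecular",
                  partner = "CycN_ox", produced = "CycN_red"),
    reaction_step("E_sq", "E_ox", params$k_cyc2, "bimolecular",
                  partner = "CycN_ox", produced = "CycN_red")
  )

  red_states <- if (explicit_binding) {
    c("E_ox", "E_ox_S", "E_red_P", "E_red")
  } else c("E_ox", "E_red_P", "E_red")

  switch(experiment,
    reductive = kinetic_scheme(
      species = c(red_states, "Pon", "P"),
      reactions = red_steps(),
      enzyme_states = red_states,
      excess = "Pon"),
    oxidation_o2 = kinetic_scheme(
      species = c("E_red", "E_ox", "O2", "H2O2"),
      reactions = list(
        reaction_step("E_red", "E_ox", params$k_ox_o2, "bimolecular",
                      partner = "O2", produced = "H2O2")),
      enzyme_states = c("E_red", "E_ox"),
      excess = "O2"),
    oxidation_cycn = kinetic_scheme(
      species = c("E_red", "E_sq", "E_ox", "CycN_ox", "CycN_red"),
      reactions = cyc_steps,
      enzyme_states = c("E_red", "E_sq", "E_ox"),
      excess = "CycN_ox"),
    full_cycle = kinetic_scheme(
      species = c(red_states, "E_sq", "Pon", "P", "CycN_ox", "CycN_red"),
      reactions = c(red_steps(), cyc_steps),
      enzyme_states = c(red_states, "E_sq"),
      excess = "Pon")
  )
}

reaction_flux <- function(r, conc) {
  switch(r$type,
    first = r$k * conc[[r$from]],
    bimolecular = r$k * conc[[r$from]] * conc[[r$partner]],
    saturating = r$k * conc[[r$sub]] / (r$Kd + conc[[r$sub]]) * conc[[r$from]]
  )
}

#' Integrate a kinetic scheme
#'
#' Stiff-capable mass-action integration (deSolve's `lsoda`) with tight
#' tolerances (absolute 1e-12 mol/L, relative 1e-8 by default). Species
#' listed in `excess` (defaulting to the scheme's own excess set) are held
#' fixed at their initial concentration.
#'
#' @param scheme A [kinetic_scheme()].
#' @param initial Named numeric vector of initial concentrations, mol/L.
#'   Species not named start at zero.
#' @param times Strictly increasing time grid starting at 0 (seconds); a
#'   leading 0 is prepended if absent.
#' @param excess Character vector overriding the scheme's excess set.
#' @param atol,rtol Integrator tolerances.
#' @return A `conc_series` object: list with `time` and a `concentrations`
#'   matrix (rows = times, columns = species).
#' @export
integrate_scheme <- function(scheme, initial, times,
                             excess = scheme$excess,
                             atol = 1e-12, rtol = 1e-8) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  y0 <- stats::setNames(numeric(length(scheme$species)), scheme$species)
  if (length(initial)) {
    bad <- setdiff(names(initial), scheme$species)
    if (length(bad)) stop("initial names not in scheme: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(!is.finite(initial)) || any(initial < 0)) {
      stop("initial concentrations must be finite and >= 0", call. = FALSE)
    }
    y0[names(initial)] <- initial
  }
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing",
                                  call. = FALSE)
  t_solve <- if (times[1] > 0) c(0, times) else times

  fixed <- scheme$species %in% excess
  rhs <- function(t, y, parms) {
    d <- numeric(length(y))
    names(d) <- names(y)
    for (r in scheme$reactions) {
      f <- reaction_flux(r, y)
      d[[r$from]] <- d[[r$from]] - f
      d[[r$to]] <- d[[r$to]] + f
      if (r$type == "bimolecular") d[[r$partner]] <- d[[r$partner]] - f
      for (p in r$produced) d[[p]] <- d[[p]] + f
    }
    d[fixed] <- 0
    list(d)
  }
  out <- deSolve::lsoda(y0, t_solve, rhs, parms = NULL,
                        atol = atol, rtol = rtol)
  if (attr(out, "istate")[1] < 0 || anyNA(out)) {
    stop("ODE integration failed to converge (lsoda istate ",
         attr(out, "istate")[1], ")", call. = FALSE)
  }
  conc <- out[match(times, t_solve), scheme$species, drop = FALSE]
  conc[conc < 0 & conc > -atol * 10] <- 0
  structure(list(time = times, concentrations = conc,
                 species = scheme$species,
                 enzyme_states = scheme$enzyme_states),
            class = "conc_series")
}

#' @export
print.conc_series <- function(x, ...) {
  cat("Concentration series:", length(x$time), "time points,",
      length(x$species), "species (",
      paste(x$species, collapse = ", "), ")\n")
  invisible(x)
}

#' First-order rate matrix of a scheme under the pseudo-first-order
#' approximation
#'
#' @param scheme A [kinetic_scheme()].
#' @param excess_concentrations Named vector of fixed concentrations (mol/L)
#'   for every bimolecular partner and saturating substrate.
#' @return Square matrix M over the enzyme states with d x/dt = M x.
#' @keywords internal
rate_matrix <- function(scheme, excess_concentrations = numeric()) {
  st <- scheme$enzyme_states
  M <- matrix(0, length(st), length(st), dimnames = list(st, st))
  for (r in scheme$reactions) {
    keff <- switch(r$type,
      first = r$k,
      bimolecular = {
        if (!(r$partner %in% names(excess_concentrations))) {
          stop("scheme is nonlinear: bimolecular partner '", r$partner,
               "' has no fixed excess concentration", call. = FALSE)
        }
        r$k * excess_concentrations[[r$partner]]
      },
      saturating = {
        if (!(r$sub %in% names(excess_concentrations))) {
          stop("saturating substrate '", r$sub,
               "' has no fixed excess concentration", call. = FALSE)
        }
        s <- excess_concentrations[[r$sub]]
        r$k * s / (r$Kd + s)
      })
    M[r$from, r$from] <- M[r$from, r$from] - keff
    M[r$to, r$from] <- M[r$to, r$from] + keff
  }
  M
}

#' Exact observed exponential rates of a linear scheme
#'
#' For a scheme that is first-order after fixing the excess species, any
#' noiseless absorbance projection is a sum of exponentials whose rates are
#' the nonzero eigenvalue magnitudes of the rate matrix. This is the analytic
#' oracle against which multi-exponential trace fits are checked.
#'
#' @inheritParams rate_matrix
#' @return Numeric vector of rates (1/s), sorted descending.
#' @examples
#' sc <- build_pnao_scheme(pnao_params(), "reductive")
#' eigenrates(sc, c(Pon = 500e-6))  # ~65.6 and 6.3 1/s
#' @export
eigenrates <- function(scheme, excess_concentrations = numeric()) {
  M <- rate_matrix(scheme, excess_concentrations)
  ev <- eigen(M, only.values = TRUE)$values
  if (max(abs(Im(ev))) > 1e-9 * max(1, max(abs(ev)))) {
    stop("complex eigenvalues: scheme is not a simple relaxation network",
         call. = FALSE)
  }
  lam <- abs(Re(ev))
  thresh <- 1e-12 * max(lam, 1)
  sort(lam[lam > thresh], decreasing = TRUE)
}
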