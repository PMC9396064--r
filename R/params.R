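#' Kinetic and thermodynamic parameter set for the Pnao catalytic cycle
#'
#' Bundles every microscopic and empirical constant used by the scheme
#' builder, the synthetic-data generators and the analysis chain. The shipped
#' defaults are the fitted values for Pnao at pH 7.5 (stopped-flow work at
#' 4 degC, potentiometry at 25 degC).
#'
#' @param k_red First-order rate constant for hydride transfer from bound
#'   pseudooxynicotine (Pon) to the flavin at saturation, 1/s.
#' @param Kd_pon Apparent dissociation constant for Pon, mol/L.
#' @param k_rel First-order rate constant for release of the imine-containing
#'   product from the reduced enzyme, 1/s.
#' @param k_ox_o2 Bimolecular rate constant, reduced flavin + O2, 1/(M s).
#' @param k_cyc1 Bimolecular rate constant, flavin hydroquinone + oxidized
#'   CycN (first one-electron transfer), 1/(M s).
#' @param k_cyc2 Bimolecular rate constant, anionic semiquinone + oxidized
#'   CycN (second one-electron transfer), 1/(M s).
#' @param k_art Rate constant of the minor concentration-invariant third
#'   phase seen at 550 nm, 1/s. Its physical origin is unresolved (damaged
#'   enzyme or instrument artifact); it is modeled empirically.
#' @param frac_art Amplitude of the minor phase as a fraction of the main
#'   550 nm amplitude, in [0, 0.1].
#' @param kcat_emp Empirical turnover number at saturating Pon and CycN, 1/s.
#' @param Km_cyc_emp Empirical Michaelis constant for CycN, mol/L.
#' @param Em_enz Midpoint potential of the oxidized/semiquinone flavin
#'   couple, mV.
#' @param n_enz Electrons transferred in the enzyme couple (1 or 2).
#' @param Em_dye Midpoint potential of the indicator dye (indigo
#'   disulfonate), mV at pH 7.5.
#' @param n_dye Electrons transferred in the dye couple (1 or 2).
#' @param temperature Stopped-flow temperature, K. Potentiometry functions
#'   take their own temperature argument (default 298.15 K).
#'
#' @return An object of class `pnao_params` (a validated named list).
#' @examples
#' p <- pnao_params()
#' p$k_red
#' @export
pnao_params <- function(k_red = 74,
                        Kd_pon = 64e-6,
                        k_rel = 6.3,
                        k_ox_o2 = 600,
                        k_cyc1 = 1.4e5,
                        k_cyc2 = 3.2e4,
                        k_art = 0.5,
                        frac_art = 0.05,
                        kcat_emp = 4.4,
                        Km_cyc_emp = 34e-6,
                        Em_enz = -111,
                        n_enz = 1L,
                        Em_dye = -139,
                        n_dye = 2L,
                        temperature = 277.15) {
  p <- list(k_red = k_red, Kd_pon = Kd_pon, k_rel = k_rel,
            k_ox_o2 = k_ox_o2, k_cyc1 = k_cyc1, k_cyc2 = k_cyc2,
            k_art = k_art, frac_art = frac_art,
            kcat_emp = kcat_emp, Km_cyc_emp = Km_cyc_emp,
            Em_enz = Em_enz, n_enz = as.integer(n_enz),
            Em_dye = Em_dye, n_dye = as.integer(n_dye),
            temperature = temperature)
  class(p) <- "pnao_params"
  validate_pnao_params(p)
  p
}

validate_pnao_params <- function(p) {
  rates <- c("k_red", "k_rel", "k_ox_o2", "k_cyc1", "k_cyc2", "k_art",
             "kcat_emp")
  for (nm in rates) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] < 0) {
      stop("parameter '", nm, "' must be a single non-negative finite number",
           call. = FALSE)
    }
  }
  if (!(p$Kd_pon > 0)) stop("Kd_pon must be > 0", call. = FALSE)
  if (!(p$Km_cyc_emp > 0)) stop("Km_cyc_emp must be > 0", call. = FALSE)
  if (!(p$n_enz %in% c(1L, 2L))) stop("n_enz must be 1 or 2", call. = FALSE)
  if (!(p$n_dye %in% c(1L, 2L))) stop("n_dye must be 1 or 2", call. = FALSE)
  if (p$frac_art < 0 || p$frac_art > 0.1) {
    stop("frac_art must lie in [0, 0.1]", call. = FALSE)
  }
  if (!(p$temperature > 0)) stop("temperature must be positive (K)",
                                 call. = FALSE)
  invisible(p)
}

#' @export
print.pnao_params <- function(x, ...) {
  cat("Pnao kinetic parameter set\n")
  cat(sprintf("  reductive half-reaction: k_red %.3g 1/s, Kd(Pon) %.3g uM, k_rel %.3g 1/s\n",
              x$k_red, x$Kd_pon * 1e6, x$k_rel))
  cat(sprintf("  oxidants: k_ox(O2) %.3g 1/(M s); k_cyc1 %.3g, k_cyc2 %.3g 1/(M s)\n",
              x$k_ox_o2, x$k_cyc1, x$k_cyc2))
  cat(sprintf("  minor 550 nm phase: k %.3g 1/s, amplitude fraction %.3g\n",
              x$k_art, x$frac_art))
  cat(sprintf("  steady state (empirical): kcat %.3g 1/s, Km(CycN) %.3g uM\n",
              x$kcat_emp, x$Km_cyc_emp * 1e6))
  cat(sprintf("  redox: Em(enzyme ox/sq) %.4g mV (n=%d), Em(dye) %.4g mV (n=%d)\n",
              x$Em_enz, x$n_enz, x$Em_dye, x$n_dye))
  invisible(x)
}

#' Write or read a parameter set as a YAML config file
#'
#' The config is a flat key-value section mirroring [pnao_params()] fields,
#' so a shipped or edited file fully determines a simulation.
#'
#' @param params A `pnao_params` object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   validated `pnao_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "pnao_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pnao_params, raw)
}
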