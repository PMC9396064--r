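#' @keywords internal
FARADAY <- 96485      # C/mol
GAS_R <- 8.314        # J/(mol K)

rt_over_f_mV <- function(temperature) 1000 * GAS_R * temperature / FARADAY

#' Equilibrium partition of delivered electrons between enzyme and dye
#'
#' Given a total electron delivery (mol/L of single-electron equivalents),
#' finds the unique solution potential E at which both couples obey their
#' Nernst relation f_red/f_ox = exp(nF(Em - E)/RT) and the electrons
#' balance: n_enz * \[E\] * f_enz + n_dye * \[dye\] * f_dye = delivered. The
#' total delivered function is strictly decreasing in E, so the root is
#' found by bisection.
#'
#' @param delivered Electron equivalents delivered, mol/L; must lie in
#'   \[0, n_enz*enzyme_conc + n_dye*dye_conc\].
#' @param params A [pnao_params()] object (couple midpoints and n values).
#' @param enzyme_conc,dye_conc Couple totals, mol/L.
#' @param temperature Temperature, K.
#' @return List with `potential_mV`, `f_enz`, `f_dye`. The degenerate
#'   endpoints return `Inf`/`-Inf` potentials with fractions exactly 0 or 1.
#' @examples
#' equilibrium_partition(0.5 * (0.4 / 11300), pnao_params(),
#'                       0.4 / 11300, 0.4 / 20200)
#' @export
equilibrium_partition <- function(delivered, params, enzyme_conc, dye_conc,
                                  temperature = 298.15) {
  validate_pnao_params(params)
  capacity <- params$n_enz * enzyme_conc + params$n_dye * dye_conc
  if (delivered < 0 || delivered > capacity * (1 + 1e-12)) {
    stop("delivered electrons outside couple capacity [0, ",
         signif(capacity, 6), "]", call. = FALSE)
  }
  rtf <- rt_over_f_mV(temperature)
  frac <- function(E, Em, n) 1 / (1 + exp(-n * (Em - E) / rtf))
  if (delivered == 0) {
    return(list(potential_mV = Inf, f_enz = 0, f_dye = 0))
  }
  if (delivered >= capacity * (1 - 1e-12)) {
    return(list(potential_mV = -Inf, f_enz = 1, f_dye = 1))
  }
  total <- function(E) {
    params$n_enz * enzyme_conc * frac(E, params$Em_enz, params$n_enz) +
      params$n_dye * dye_conc * frac(E, params$Em_dye, params$n_dye) -
      delivered
  }
  lo <- min(params$Em_enz, params$Em_dye) - 1500
  hi <- max(params$Em_enz, params$Em_dye) + 1500
  root <- stats::uniroot(total, c(lo, hi), tol = 1e-9)$root
  list(potential_mV = root,
       f_enz = frac(root, params$Em_enz, params$n_enz),
       f_dye = frac(root, params$Em_dye, params$n_dye))
}

#' Linearized Nernst analysis of a titration series
#'
#' Regresses ln(red/ox) of the enzyme couple on ln(red/ox) of the dye over
#' steps where both fractions lie inside `window`. Deriving both couples'
#' Nernst relations gives
#' slope = n_enz/n_dye and intercept = (n_enz F / RT)(Em_enz - Em_dye), so
#' the enzyme midpoint is recovered as
#' Em_enz = Em_dye + intercept * RT/(n_enz F). (The commonly printed
#' single-couple form fixes the slope at 1 and flips the intercept sign;
#' the derived two-couple form is used here — see the methods vignette.)
#'
#' When the series carries absorbance noise, the fractions entering the
#' regression are recomputed from the recorded band absorbances using the
#' band extinction conventions and the couple totals stored on the series
#' (the analyst's knowledge of the extinction coefficients and measured
#' concentrations), so each step's noise enters independently.
#'
#' @param series A `titration_series` from [generate_titration()].
#' @param window Fraction-reduced bounds; steps with either couple outside
#'   are excluded (default c(0.1, 0.9)).
#' @param n_enz Electrons of the enzyme couple (default from the series).
#' @param use_absorbance If `TRUE` (default when the series is noisy),
#'   derive fractions from the recorded absorbances.
#' @return List with `Em_enz_mV`, `slope`, `intercept`, standard errors,
#'   and the number of steps used.
#' @export
nernst_fit <- function(series, window = c(0.1, 0.9),
                       n_enz = attr(series, "n_enz"),
                       use_absorbance = attr(series, "noise_sd") > 0) {
  stopifnot(inherits(series, "titration_series"))
  Em_dye <- attr(series, "Em_dye")
  rtf <- rt_over_f_mV(attr(series, "temperature"))
  if (isTRUE(use_absorbance)) {
    e_tot <- attr(series, "enzyme_conc")
    d_tot <- attr(series, "dye_conc")
    # band conventions: enzyme ox 11300 -> anionic semiquinone 4000 at the
    # flavin band; oxidized dye 20200 at 600 nm, reduced colorless
    f_enz <- (e_tot * 11300 - series$A_enz) / (e_tot * (11300 - 4000))
    f_dye <- 1 - series$A_dye / (d_tot * 20200)
  } else {
    f_enz <- series$f_enz
    f_dye <- series$f_dye
  }
  keep <- f_enz > window[1] & f_enz < window[2] &
    f_dye > window[1] & f_dye < window[2]
  if (sum(keep) < 5) {
    stop("fewer than 5 steps with both couples inside the window",
         call. = FALSE)
  }
  x <- log(f_dye[keep] / (1 - f_dye[keep]))
  y <- log(f_enz[keep] / (1 - f_enz[keep]))
  fit <- stats::lm(y ~ x)
  # noiseless series fit exactly; the perfect-fit warning is expected there
  co <- suppressWarnings(summary(fit)$coefficients)
  intercept <- co[1, 1]
  list(Em_enz_mV = Em_dye + intercept * rtf / n_enz,
       slope = co[2, 1], slope_se = co[2, 2],
       intercept = intercept, intercept_se = co[1, 2],
       Em_se_mV = co[1, 2] * rtf / n_enz,
       n_used = sum(keep))
}
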