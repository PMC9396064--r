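# Shared fixtures: default parameters and a small fast instrument for
# cheap tests (fewer points, quiet noise unless a test turns it on).

default_params <- pnao_params()

quiet_instrument <- function(seed = 1L, n_points = 200L) {
  instrument_model(noise_sd = 0, n_points = n_points, seed = seed)
}

noisy_instrument <- function(seed = 1L, n_points = 300L) {
  instrument_model(noise_sd = 0.002, n_points = n_points, seed = seed)
}

# exact sequential-chain concentrations A -> B -> C, a closed form used as
# the integrator oracle
chain_closed_form <- function(t, k1, k2, a0 = 1) {
  a <- a0 * exp(-k1 * t)
  b <- a0 * k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  list(a = a, b = b, c = a0 - a - b)
}

# reciprocal-wait cycle flux at saturating Pon
cycle_flux <- function(p, cycn, pon = 1e-3) {
  keff <- p$k_red * pon / (p$Kd_pon + pon)
  1 / (1 / keff + 1 / p$k_rel + 1 / (p$k_cyc1 * cycn) + 1 / (p$k_cyc2 * cycn))
}
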