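test_that("identical seeds give bit-identical datasets", {
  a <- generate_reductive(default_params, c(100e-6, 500e-6),
                          noisy_instrument(seed = 42))
  b <- generate_reductive(default_params, c(100e-6, 500e-6),
                          noisy_instrument(seed = 42))
  expect_identical(a, b)
  c1 <- generate_reductive(default_params, c(100e-6, 500e-6),
                           noisy_instrument(seed = 43))
  expect_false(identical(a[[1]]$absorbance, c1[[1]]$absorbance))

  t1 <- generate_titration(default_params, noise_sd = 0.005, seed = 7)
  t2 <- generate_titration(default_params, noise_sd = 0.005, seed = 7)
  expect_identical(t1, t2)

  s1 <- generate_steady_state(default_params, seed = 9)
  s2 <- generate_steady_state(default_params, seed = 9)
  expect_identical(s1, s2)
})

test_that("noiseless reductive traces are biexponential at the eigenrates", {
  tr <- generate_reductive(default_params, 500e-6, quiet_instrument())[[1]]
  f <- fit_exponentials(tr, 2)
  expect_true(f$converged)
  expect_equal(f$rates, c(74 * 500 / 564, 6.3), tolerance = 1e-4)
  # first phase carries ~65% of the 450 nm amplitude at 500 uM Pon
  expect_equal(abs(f$amplitudes[1]) / sum(abs(f$amplitudes)), 0.65,
               tolerance = 0.01)
})

test_that("reductive traces complete within 0.8 s at >= 250 uM Pon", {
  trs <- generate_reductive(default_params, c(250e-6, 500e-6),
                            quiet_instrument())
  for (tr in trs) {
    total <- diff(range(tr$absorbance))
    at_08 <- tr$absorbance[which.min(abs(tr$time - 0.8))]
    expect_lt(abs(at_08 - tr$absorbance[length(tr$time)]), 0.01 * total)
  }
})

test_that("O2 traces are single exponentials with rate k_ox_o2 * [O2]", {
  tr <- generate_oxidation_o2(default_params, 600e-6, quiet_instrument())[[1]]
  f <- fit_exponentials(tr, 1)
  expect_equal(f$rates, 0.36, tolerance = 1e-4)
  # ~95% recovery by three time constants (~8.3 s), well inside a 20 s window
  i95 <- which(tr$absorbance - min(tr$absorbance) >=
                 0.95 * diff(range(tr$absorbance)))[1]
  expect_equal(tr$time[i95], 3 / 0.36, tolerance = 0.1)
})

test_that("CycN traces: biexponential rise at the eigenrates with the
           stoichiometric amplitude when the minor phase is off", {
  p0 <- pnao_params(frac_art = 0)
  tr <- generate_oxidation_cycn(p0, 50e-6, quiet_instrument())[[1]]
  f <- fit_exponentials(tr, 2)
  expect_equal(f$rates, c(7.0, 1.6), tolerance = 1e-4)
  expect_equal(sum(abs(f$amplitudes)), 21000 * 2 * 5e-6, tolerance = 0.01)
})

test_that("the minor 550 nm phase appears at k_art with ~5% amplitude", {
  tr <- generate_oxidation_cycn(default_params, 160e-6,
                                quiet_instrument(n_points = 300))[[1]]
  f <- fit_exponentials(tr, 3)
  lab <- assign_cycn_phases(f)
  expect_equal(lab$k_minor, 0.5, tolerance = 0.02)
  minor_amp <- abs(f$amplitudes[which.min(abs(f$amplitudes))])
  expect_equal(minor_amp / (21000 * 2 * 5e-6), 0.05, tolerance = 0.01)
})

test_that("sub-stoichiometric CycN mixes are rejected", {
  expect_error(generate_oxidation_cycn(default_params, 5e-6,
                                       quiet_instrument()),
               "excess-oxidant")
})

test_that("trace noise is Gaussian with the configured sd", {
  inst <- instrument_model(noise_sd = 0.002, n_points = 1500, seed = 11)
  noisy <- generate_reductive(default_params, 250e-6, inst)[[1]]
  clean <- generate_reductive(default_params, 250e-6,
                              instrument_model(noise_sd = 0,
                                               n_points = 1500))[[1]]
  res <- noisy$absorbance - clean$absorbance
  expect_equal(sd(res), 0.002, tolerance = 0.1)
  expect_gt(shapiro.test(res)$p.value, 0.001)
})

test_that("empirical steady-state velocities follow the Michaelis-Menten law", {
  ds <- generate_steady_state(default_params, cv = 0, replicates = 1)
  km <- default_params$Km_cyc_emp
  v_at_km <- generate_steady_state(default_params, cycn_concs = c(km, 2 * km,
                                                                  4 * km, 8 * km, 100 * km),
                                   cv = 0, replicates = 1)
  expect_equal(v_at_km$velocity[1], default_params$kcat_emp / 2,
               tolerance = 1e-10)
  expect_equal(v_at_km$velocity[5], default_params$kcat_emp,
               tolerance = 0.01)
  expect_true(all(ds$velocity >= 0))
  expect_error(generate_steady_state(default_params, replicates = 0),
               "replicates")
})

test_that("mechanistic steady-state velocities match the reciprocal-wait flux", {
  ds <- generate_steady_state(default_params,
                              cycn_concs = c(10, 40, 160) * 1e-6,
                              mode = "mechanistic")
  v_pred <- cycle_flux(default_params, c(10, 40, 160) * 1e-6)
  expect_equal(ds$velocity, v_pred, tolerance = 0.02)
})

test_that("titrations conserve electrons and move monotonically", {
  tit <- generate_titration(default_params, steps = 40)
  etot <- attr(tit, "enzyme_conc") * default_params$n_enz * tit$f_enz +
    attr(tit, "dye_conc") * default_params$n_dye * tit$f_dye
  expect_lt(max(abs(etot - tit$delivered)), 1e-9)
  expect_true(all(diff(tit$delivered) >= 0))
  pot <- tit$potential_mV[is.finite(tit$potential_mV)]
  expect_true(all(diff(pot) < 0))
  expect_equal(c(tit$f_enz[1], tit$f_dye[1]), c(0, 0))
  expect_equal(c(tit$f_enz[40], tit$f_dye[40]), c(1, 1))
})
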