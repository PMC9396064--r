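synthetic_trace <- function(t, amps, rates, A_inf, noise = 0, seed = 1) {
  y <- A_inf + rowSums(sapply(seq_along(rates),
                              function(i) amps[i] * exp(-rates[i] * t)))
  if (noise > 0) {
    set.seed(seed)
    y <- y + rnorm(length(t), 0, noise)
  }
  sf_trace(t, y, 450)
}

test_that("exact recovery on a noiseless single exponential", {
  t <- exp(seq(log(0.002), log(1), length.out = 200))
  tr <- synthetic_trace(t, -0.1, 10, 0.05)
  f <- fit_exponentials(tr, 1)
  expect_true(f$converged)
  expect_equal(f$rates, 10, tolerance = 1e-6)
  expect_equal(f$amplitudes, -0.1, tolerance = 1e-6)
  expect_equal(f$A_inf, 0.05, tolerance = 1e-6)
})

test_that("noiseless fitted rates equal scheme eigenrates (oracle equivalence)", {
  # across experiment classes and concentrations
  cases <- list(
    list(gen = function(c, i) generate_reductive(default_params, c, i),
         conc = c(100e-6, 500e-6), phases = 2,
         rates = function(c) c(74 * c / (64e-6 + c), 6.3)),
    list(gen = function(c, i) generate_oxidation_o2(default_params, c, i),
         conc = c(150e-6, 1200e-6), phases = 1,
         rates = function(c) 600 * c))
  for (case in cases) {
    for (cc in case$conc) {
      tr <- case$gen(cc, quiet_instrument())[[1]]
      f <- fit_exponentials(tr, case$phases)
      expect_equal(f$rates, case$rates(cc), tolerance = 1e-4)
    }
  }
})

test_that("saturated points are excluded from fits", {
  t <- exp(seq(log(0.002), log(1), length.out = 300))
  y <- 2 * exp(-5 * t) + 0.2
  tr <- sf_trace(t, y, 550, saturated = y > 1.5)
  expect_gt(sum(tr$saturated), 10)
  f <- fit_exponentials(tr, 1)
  expect_equal(f$rates, 5, tolerance = 1e-6)
  expect_equal(f$n, sum(!tr$saturated))
})

test_that("phase-count selection by BIC matches the trace structure", {
  t <- exp(seq(log(0.002), log(1), length.out = 300))
  expect_identical(select_phase_count(synthetic_trace(t, -0.1, 10, 0.05)), 1L)
  tr2 <- generate_reductive(default_params, 500e-6,
                            noisy_instrument(seed = 3))[[1]]
  expect_identical(select_phase_count(tr2), 2L)
  tr3 <- generate_oxidation_cycn(default_params, 80e-6,
                                 noisy_instrument(seed = 4))[[1]]
  expect_identical(select_phase_count(tr3), 3L)
})

test_that("hyperbolic secondary fit recovers k_red and Kd from exact points", {
  conc <- c(25, 50, 100, 150, 250, 375, 500) * 1e-6
  pts <- data.frame(conc = conc, k_obs = 74 * conc / (64e-6 + conc))
  f <- fit_secondary(pts, "hyperbolic")
  expect_equal(f$k_red, 74, tolerance = 1e-6)
  expect_equal(f$Kd, 64e-6, tolerance = 1e-6)
  expect_false(f$unidentifiable)
})

test_that("linear secondary fit recovers a slope through the origin", {
  conc <- c(75, 150, 300, 600, 1200) * 1e-6
  pts <- data.frame(conc = conc, k_obs = 600 * conc)
  f <- fit_secondary(pts, "linear")
  expect_equal(f$slope, 600, tolerance = 1e-8)
  expect_equal(f$intercept, 0, tolerance = 1e-8)
})

test_that("constant secondary fit is the (weighted) mean", {
  pts <- data.frame(conc = c(1, 2, 3, 4) * 1e-6,
                    k_obs = c(6.2, 6.4, 6.3, 6.3))
  f <- fit_secondary(pts, "constant")
  expect_equal(f$mean, 6.3, tolerance = 1e-12)
  pts$se <- c(0.1, 0.1, 0.1, 1e6)  # the wild point carries no weight
  pts$k_obs[4] <- 60
  f2 <- fit_secondary(pts, "constant")
  expect_equal(f2$mean, mean(c(6.2, 6.4, 6.3)), tolerance = 1e-3)
})

test_that("hyperbolic fit flags an unidentifiable Kd on linear data", {
  conc <- c(1, 2, 3, 4, 5) * 1e-6
  pts <- data.frame(conc = conc, k_obs = 1e5 * conc)
  f <- fit_secondary(pts, "hyperbolic")
  expect_true(f$unidentifiable)
  # and its implied small-[S] slope matches the data slope within 2%
  expect_equal(f$k_red / f$Kd, 1e5, tolerance = 0.02)
})

test_that("too few concentrations are rejected", {
  expect_error(fit_secondary(data.frame(conc = c(1e-6, 2e-6),
                                        k_obs = c(1, 2)), "linear"),
               ">= 3")
  expect_error(fit_secondary(data.frame(conc = c(1e-6, 2e-6, 3e-6),
                                        k_obs = c(1, 2, 3)), "hyperbolic"),
               ">= 4")
})

test_that("traces with too few unsaturated points are rejected", {
  t <- seq(0.01, 1, length.out = 15)
  tr <- sf_trace(t, exp(-t), 450, saturated = rep(c(TRUE, FALSE), c(10, 5)))
  expect_error(fit_exponentials(tr, 1), "unsaturated")
})
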