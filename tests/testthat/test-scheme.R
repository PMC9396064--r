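test_that("scheme builder returns the documented topology per experiment", {
  sc <- build_pnao_scheme(default_params, "oxidation_cycn")
  expect_length(sc$reactions, 2)
  expect_true(all(vapply(sc$reactions, function(r) r$type, "") == "bimolecular"))
  expect_length(sc$enzyme_states, 3)

  sc_red <- build_pnao_scheme(default_params, "reductive")
  expect_length(sc_red$reactions, 2)
  sc_full <- build_pnao_scheme(default_params, "full_cycle")
  expect_length(sc_full$reactions, 4)
  expect_error(build_pnao_scheme(default_params, "photolysis"),
               "unknown experiment")
})

test_that("zero substrate freezes the reductive scheme", {
  sc <- build_pnao_scheme(default_params, "reductive")
  ser <- integrate_scheme(sc, c(E_ox = 17.5e-6, Pon = 0),
                          seq(0.01, 1, by = 0.01))
  expect_equal(max(abs(ser$concentrations[, "E_ox"] - 17.5e-6)), 0,
               tolerance = 1e-12)
})

test_that("all-zero rate constants give a constant trajectory", {
  sc <- kinetic_scheme(c("A", "B"), list(reaction_step("A", "B", 0, "first")),
                       enzyme_states = c("A", "B"))
  ser <- integrate_scheme(sc, c(A = 1e-6), seq(0.1, 10, by = 0.1))
  expect_true(all(ser$concentrations[, "A"] == 1e-6))
  expect_true(all(ser$concentrations[, "B"] == 0))
})

test_that("integrator matches the closed-form sequential chain", {
  k1 <- 5; k2 <- 1
  sc <- kinetic_scheme(c("A", "B", "C"),
                       list(reaction_step("A", "B", k1, "first"),
                            reaction_step("B", "C", k2, "first")),
                       enzyme_states = c("A", "B", "C"))
  tg <- exp(seq(log(0.001), log(5), length.out = 150))
  ser <- integrate_scheme(sc, c(A = 1), tg)
  cf <- chain_closed_form(tg, k1, k2)
  expect_equal(ser$concentrations[, "C"], unname(cf$c), tolerance = 1e-6)
  expect_equal(ser$concentrations[, "A"], unname(cf$a), tolerance = 1e-6)
})

test_that("integrator agrees with the matrix-exponential solution for a
           pseudo-first-order Pnao scheme", {
  skip_if_not_installed("Matrix")
  sc <- build_pnao_scheme(default_params, "reductive")
  M <- pnaokin:::rate_matrix(sc, c(Pon = 500e-6))
  tg <- exp(seq(log(0.002), log(1), length.out = 40))
  ser <- integrate_scheme(sc, c(E_ox = 17.5e-6, Pon = 500e-6), tg)
  x0 <- c(17.5e-6, 0, 0)
  for (i in c(1, 20, 40)) {
    xt <- as.numeric(Matrix::expm(M * tg[i]) %*% x0)
    expect_equal(unname(ser$concentrations[i, sc$enzyme_states]), xt,
                 tolerance = 1e-6)
  }
})

test_that("enzyme-state and CycN mass are conserved during integration", {
  sc <- build_pnao_scheme(default_params, "oxidation_cycn")
  tg <- exp(seq(log(0.001), log(20), length.out = 100))
  # full bimolecular integration (no excess lumping)
  ser <- integrate_scheme(sc, c(E_red = 17.5e-6, CycN_ox = 50e-6), tg,
                          excess = character())
  etot <- rowSums(ser$concentrations[, sc$enzyme_states])
  ctot <- rowSums(ser$concentrations[, c("CycN_ox", "CycN_red")])
  expect_lt(max(abs(etot / 17.5e-6 - 1)), 1e-6)
  expect_lt(max(abs(ctot / 50e-6 - 1)), 1e-6)
  # monotone oxidant consumption
  expect_true(all(diff(ser$concentrations[, "CycN_red"]) >= -1e-15))
})

test_that("stoichiometric bookkeeping: two CycN reduced per enzyme", {
  sc <- build_pnao_scheme(default_params, "oxidation_cycn")
  ser <- integrate_scheme(sc, c(E_red = 17.5e-6, CycN_ox = 200e-6),
                          exp(seq(log(0.01), log(60), length.out = 80)))
  expect_equal(ser$concentrations[nrow(ser$concentrations), "CycN_red"],
               c(CycN_red = 35e-6), tolerance = 1e-5)
})

test_that("eigenrates returns the observed exponential rates", {
  sc <- build_pnao_scheme(default_params, "reductive")
  expect_equal(eigenrates(sc, c(Pon = 500e-6)),
               c(74 * 500 / 564, 6.3), tolerance = 1e-10)
  sc2 <- build_pnao_scheme(default_params, "oxidation_cycn")
  expect_equal(eigenrates(sc2, c(CycN_ox = 50e-6)), c(7.0, 1.6),
               tolerance = 1e-10)
  sc3 <- build_pnao_scheme(default_params, "oxidation_o2")
  expect_equal(eigenrates(sc3, c(O2 = 600e-6)), 0.36, tolerance = 1e-10)
  # nonlinear scheme (no excess concentration for the partner) is rejected
  expect_error(eigenrates(sc2, numeric()), "nonlinear")
})

test_that("negative initial concentrations and bad grids are rejected", {
  sc <- build_pnao_scheme(default_params, "oxidation_o2")
  expect_error(integrate_scheme(sc, c(E_red = -1e-6), c(0.1, 1)), ">= 0")
  expect_error(integrate_scheme(sc, c(E_red = 1e-6), c(0.5, 0.4)),
               "strictly increasing")
})
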