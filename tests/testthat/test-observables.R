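make_series <- function(time, conc_list) {
  species <- names(conc_list)
  m <- do.call(cbind, conc_list)
  colnames(m) <- species
  structure(list(time = time, concentrations = m, species = species,
                 enzyme_states = character()), class = "conc_series")
}

test_that("Beer-Lambert projection reproduces the printed arithmetic", {
  tg <- seq(0.01, 1, length.out = 20)
  # all-zero concentrations project to zero absorbance
  z <- make_series(tg, list(CycN_red = rep(0, 20)))
  expect_true(all(project_absorbance(z, wavelength = 550)$absorbance == 0))

  # complete reduction of 10 uM CycN at 550 nm: dA = 21000 * 1e-5 = 0.21
  s <- make_series(tg, list(CycN_red = seq(0, 10e-6, length.out = 20)))
  tr <- project_absorbance(s, wavelength = 550)
  expect_equal(diff(range(tr$absorbance)), 0.21, tolerance = 1e-12)

  # 20 uM oxidized CycN at 410 nm: A = 101600 * 2e-5 = 2.032, saturated
  s2 <- make_series(tg, list(CycN_ox = rep(20e-6, 20)))
  tr2 <- project_absorbance(s2, wavelength = 410)
  expect_equal(tr2$absorbance[1], 2.032, tolerance = 1e-12)
  expect_true(all(tr2$saturated))
})

test_that("default table carries the 21,000 CycN difference coefficient", {
  e <- default_extinction_entries()
  d550 <- e$epsilon[e$species == "CycN_red" & e$wavelength == 550] -
    e$epsilon[e$species == "CycN_ox" & e$wavelength == 550]
  expect_identical(d550, 21000)
})

test_that("projection is linear in the trajectories", {
  tg <- seq(0.01, 1, length.out = 30)
  a <- make_series(tg, list(CycN_red = seq(0, 5e-6, length.out = 30),
                            CycN_ox = rep(1e-6, 30)))
  b <- make_series(tg, list(CycN_red = rep(2e-6, 30),
                            CycN_ox = seq(3e-6, 0, length.out = 30)))
  ab <- make_series(tg, list(CycN_red = a$concentrations[, 1] + b$concentrations[, 1],
                             CycN_ox = a$concentrations[, 2] + b$concentrations[, 2]))
  expect_equal(project_absorbance(ab, wavelength = 550)$absorbance,
               project_absorbance(a, wavelength = 550)$absorbance +
                 project_absorbance(b, wavelength = 550)$absorbance,
               tolerance = 1e-12)
})

test_that("species without a table entry warn and project as zero", {
  tg <- seq(0.01, 1, length.out = 20)
  s <- make_series(tg, list(mystery = rep(1e-6, 20)))
  expect_warning(tr <- project_absorbance(s, wavelength = 550), "mystery")
  expect_true(all(tr$absorbance == 0))
})

test_that("out-of-band wavelengths are rejected", {
  tg <- seq(0.01, 1, length.out = 20)
  s <- make_series(tg, list(CycN_red = rep(1e-6, 20)))
  expect_error(project_absorbance(s, wavelength = 150), "wavelength")
  expect_error(project_absorbance(s, wavelength = 900), "wavelength")
})

test_that("550 nm amplitude of a CycN oxidation equals two electrons of enzyme", {
  sc <- build_pnao_scheme(default_params, "oxidation_cycn")
  tg <- exp(seq(log(1e-4), log(30), length.out = 150))
  ser <- integrate_scheme(sc, c(E_red = 5e-6, CycN_ox = 100e-6), tg)
  tr <- project_absorbance(ser, wavelength = 550)
  expect_equal(diff(range(tr$absorbance)), 21000 * 2 * 5e-6,
               tolerance = 1e-3)
})
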