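kd_paper <- 5.2e-16

test_that("species_fractions solves the T3M mass balance (bisection oracle)", {
  m <- equilibrium_model("T3M", kd = kd_paper)

  # dilution limit
  expect_equal(species_fractions(m, 1e-15)$f_monomer, 1, tolerance = 1e-4)

  # independent bisection oracle on the cubic at 40 nM
  f <- function(M) M + 3 * M^3 / kd_paper - 4.0e-8
  lo <- 0; hi <- 4.0e-8
  for (i in 1:200) { mid <- (lo + hi) / 2; if (f(mid) < 0) lo <- mid else hi <- mid }
  sf <- species_fractions(m, 4.0e-8)
  expect_equal(sf$M, lo, tolerance = 1e-10)
  expect_equal(sf$f_monomer, 0.402, tolerance = 1e-2)
  expect_equal(sf$f_trimer, 0.598, tolerance = 1e-2)

  expect_error(species_fractions(m, -1), "positive")
  expect_error(equilibrium_model("T3M", kd = -5), "positive")
})

test_that("mass conservation, monotonicity and scale equivariance hold", {
  m <- equilibrium_model("T3M", kd = kd_paper)
  cc <- 10^seq(-10, -4, length.out = 25)
  sf <- species_fractions(m, cc)
  expect_lt(max(abs(sf$M + 2 * sf$D + 3 * sf$T - cc) / cc), 1e-10)
  expect_true(all(diff(sf$f_monomer) < 0))
  expect_true(all(sf$f_monomer >= 0 & sf$f_monomer <= 1))

  # multiplying concentrations by c and Kd by c^2 leaves fractions unchanged
  c_fac <- 137
  m2 <- equilibrium_model("T3M", kd = kd_paper * c_fac^2)
  expect_equal(monomer_fraction(m2, cc * c_fac), sf$f_monomer, tolerance = 1e-12)
})

test_that("the dimer-containing scheme reduces to T3M as K2 grows", {
  m3 <- equilibrium_model("T3M", kd = kd_paper)
  mx <- equilibrium_model("T3_D2_M", k1 = kd_paper / 1e6, k2 = 1e6)
  cc <- c(6e-9, 4e-8, 2e-6)
  expect_equal(monomer_fraction(mx, cc), monomer_fraction(m3, cc), tolerance = 1e-6)

  # with a real dimer population, mass balance still closes
  md <- equilibrium_model("T3_D2_M", k1 = 1e-8, k2 = 5.2e-8)
  sf <- species_fractions(md, 1e-6)
  expect_equal(sf$M + 2 * sf$D + 3 * sf$T, 1e-6, tolerance = 1e-10)
  expect_gt(sf$f_dimer, 0)
  expect_equal(sf$f_monomer + sf$f_dimer + sf$f_trimer, 1, tolerance = 1e-10)
})

test_that("fit_dissociation is self-consistent on noiseless data", {
  m <- equilibrium_model("T3M", kd = kd_paper)
  conc <- 10^seq(log10(2e-9), log10(2e-5), length.out = 12)
  dat <- gen_titration(m, conc, noise_sd = 0, seed = 1)
  fit <- fit_dissociation(dat, n_bootstrap = 0)
  expect_equal(fit$log10_kd, log10(kd_paper), tolerance = 1e-6)
})

test_that("fit_dissociation recovers Kd from noisy replicates and reports CIs", {
  m <- equilibrium_model("T3M", kd = kd_paper)
  conc <- 10^seq(log10(2e-9), log10(2e-5), length.out = 12)
  kds <- vapply(1:25, function(s) {
    fit_dissociation(gen_titration(m, conc, noise_sd = 0.03, seed = s),
                     n_bootstrap = 0)$kd
  }, numeric(1))
  expect_lt(abs(median(kds) - kd_paper) / kd_paper, 0.20)

  fit <- fit_dissociation(gen_titration(m, conc, noise_sd = 0.03, seed = 1),
                          n_bootstrap = 50, seed = 9)
  expect_length(fit$ci, 2L)
  expect_lt(fit$ci[1], fit$kd)
  expect_gt(fit$ci[2], fit$kd)
  # deterministic given the seed
  fit2 <- fit_dissociation(gen_titration(m, conc, noise_sd = 0.03, seed = 1),
                           n_bootstrap = 50, seed = 9)
  expect_identical(fit$ci, fit2$ci)
})

test_that("fit_dissociation validates its inputs", {
  expect_error(fit_dissociation(titration_dataset(c(1e-8, 2e-8, 3e-8), c(1, 1, 1))),
               "at least 4")
  narrow <- titration_dataset(c(1e-8, 1.2e-8, 1.5e-8, 2e-8), c(0.9, 0.85, 0.8, 0.75))
  expect_error(fit_dissociation(narrow), "decades")
})

test_that("perrin_hydro reproduces closed-form Stokes-Einstein and Perrin values", {
  sph <- perrin_hydro(19.5, 19.5, temperature = 293, viscosity = 1.002e-3)
  d_oracle <- 1.380649e-23 * 293 / (6 * pi * 1.002e-3 * 19.5e-10) * 1e12
  expect_equal(sph$d_trans, d_oracle, tolerance = 1e-10)
  expect_identical(sph$shape, "sphere")

  # prolate monomer-like spheroid: R_h from the closed-form Perrin factor
  pro <- perrin_hydro(24, 17.6, temperature = 293)
  p <- 17.6 / 24; xi <- sqrt(1 - p^2)
  expect_equal(pro$r_hydro, 24 * xi / log((1 + xi) / p), tolerance = 1e-12)
  expect_equal(pro$r_hydro, 19.69, tolerance = 1e-3)
  expect_equal(pro$d_trans, 108.8, tolerance = 1e-2)

  # oblate trimer-like disk
  obl <- perrin_hydro(20, 41.3, temperature = 293)
  p2 <- 20 / 41.3; xi2 <- sqrt(1 - p2^2)
  expect_equal(obl$r_hydro, 41.3 * xi2 / atan(xi2 / p2), tolerance = 1e-12)
  expect_equal(obl$r_hydro, 33.91, tolerance = 1e-3)
  expect_equal(obl$d_trans, 63.1, tolerance = 1e-2)

  expect_error(perrin_hydro(-1, 5), "positive")
})

test_that("Perrin factor limits: sphere continuity and volume-equivalent bound", {
  # R_h -> radius as the axial ratio -> 1
  expect_equal(perrin_hydro(10 * (1 + 1e-10), 10)$r_hydro, 10, tolerance = 1e-8)
  expect_equal(perrin_hydro(10, 10 * (1 + 1e-10))$r_hydro, 10, tolerance = 1e-8)

  # R_h >= volume-equivalent radius for axial ratios across (0.1, 10)
  for (ratio in c(0.1, 0.3, 0.7, 1.5, 3, 10)) {
    a <- 10 * ratio; b <- 10
    h <- perrin_hydro(a, b)
    r_vol <- (a * b^2)^(1 / 3)
    expect_gte(h$r_hydro, r_vol - 1e-9)
  }
})
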