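test_that("duplex fraction obeys the mass-action equilibrium", {
  # half-duplexed at the two-state Tm: K * CT/4 = 1 with equal strands
  dH <- -60; dS <- -170
  Tm <- melting_temperature(dH, dS, 1e-6, FALSE)
  f <- duplex_fraction(Tm, dH, dS, 5e-7, 5e-7)
  expect_equal(f, 0.5, tolerance = 1e-6)
  # low-temperature limit: essentially everything duplexed
  expect_gt(duplex_fraction(273.15, dH, dS, 5e-7, 5e-7), 0.99)
  expect_equal(duplex_fraction(250, dH, dS, 5e-7, 5e-7), 1, tolerance = 1e-4)
  # unequal strands, strong association: limiting strand saturates and the
  # result matches an independent numerical equilibrium solve
  cA <- 1e-6; cB <- 5e-7
  Tlow <- 290
  f2 <- duplex_fraction(Tlow, dH, dS, cA, cB)
  K <- exp(-(dH * 1000 - Tlow * dS) / (1.987 * Tlow))
  root <- uniroot(function(d) K * (cA - d) * (cB - d) - d,
                  c(0, cB * (1 - 1e-12)), tol = 1e-18)$root
  expect_equal(f2, root / cB, tolerance = 1e-6)
  # monotone non-increasing in temperature
  Ts <- seq(280, 370, by = 1)
  fs <- duplex_fraction(Ts, dH, dS, cA, cB)
  expect_true(all(diff(fs) <= 1e-12))
})

test_that("simulated absorbance respects strand conservation and hypochromicity", {
  bl <- pzfold:::default_melt_baselines()
  tr <- pzfold:::default_melt_truth(c(1, 1, 1, 1))
  grid <- seq(15, 95, by = 2)
  # zero hypochromicity and zero slope: curve equals the baseline sum
  tr0 <- global_melt_model(tr$dH, tr$dS, 1e-12, 0, tr$conc)
  sim0 <- simulate_melt(tr0, bl, grid)
  for (m in 1:2) {
    base <- tr$conc[m, 1] * bl[[1]](grid) + tr$conc[m, 2] * bl[[2]](grid)
    expect_equal(sim0[[m]]$absorbance, base, tolerance = 1e-9)
  }
  # total strand counts are conserved: duplex + free A + free B = totals,
  # visible as the absorbance interpolating between duplex and ss limits
  sim <- simulate_melt(tr, bl, grid)
  for (m in 1:2) {
    ss_limit <- tr$conc[m, 1] * bl[[1]](grid) + tr$conc[m, 2] * bl[[2]](grid)
    expect_true(all(sim[[m]]$absorbance <= ss_limit + 1e-9))
  }
})

test_that("sharper transitions come from more negative enthalpy at fixed Tm", {
  CT4 <- 2.5e-7
  Tm <- 330
  mk <- function(dH) {
    dS <- dH * 1000 / Tm - 1.987 * log(CT4)
    function(T) duplex_fraction(T, dH, dS, 5e-7, 5e-7)
  }
  shallow <- mk(-50); steep <- mk(-90)
  expect_equal(shallow(Tm), 0.5, tolerance = 1e-6)
  expect_equal(steep(Tm), 0.5, tolerance = 1e-6)
  expect_lt(steep(Tm + 4), shallow(Tm + 4))
  expect_gt(steep(Tm - 4), shallow(Tm - 4))
})

test_that("noise-free simulate-then-fit round-trips the truth", {
  bl <- pzfold:::default_melt_baselines()
  tr <- pzfold:::default_melt_truth(c(1, 1, 1, 1))
  fx <- gen_melt_fixture(tr, bl, grid = seq(15, 95, by = 1), noise_rel = 0,
                         seed = 3)
  gf <- global_fit(fx$curves, bl, fx$nominal_CT, seed = 5)
  expect_lt(abs(gf$model$dH - tr$dH) / abs(tr$dH), 1e-3)
  expect_lt(abs(gf$model$dS - tr$dS) / abs(tr$dS), 1e-3)
  expect_lt(gf$ssr, 1e-6)
  expect_equal(gf$dG37, gf$model$dH - 310.15 * gf$model$dS / 1000)
})

test_that("planted pipetting errors are recovered in the fitted concentrations", {
  bl <- pzfold:::default_melt_baselines()
  tr <- pzfold:::default_melt_truth(c(1.05, 0.95, 1.05, 0.95))
  fx <- gen_melt_fixture(tr, bl, grid = seq(15, 95, by = 1), noise_rel = 0,
                         seed = 4)
  gf <- global_fit(fx$curves, bl, fx$nominal_CT, seed = 6)
  expect_equal(unname(gf$model$conc), unname(tr$conc), tolerance = 0.01)
  expect_equal(gf$concentration_deviation, 0.05, tolerance = 0.15)
  expect_equal(gf$chosen_assignment, "AA")
})

test_that("fixture reproducibility: same seed, identical curves", {
  bl <- pzfold:::default_melt_baselines()
  tr <- pzfold:::default_melt_truth()
  f1 <- gen_melt_fixture(tr, bl, seed = 42)
  f2 <- gen_melt_fixture(tr, bl, seed = 42)
  expect_identical(f1$curves, f2$curves)
  f3 <- gen_melt_fixture(tr, bl, seed = 43)
  expect_false(identical(f1$curves[[1]]$absorbance, f3$curves[[1]]$absorbance))
})
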