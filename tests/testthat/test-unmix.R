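test_that("the mixture model reproduces pure references, flat baselines and averages", {
  refs <- truthRefs()
  # p1 = 1, everything else 0: the S reference spectrum itself
  sp <- modelSpectrum(c(1, 0, 0), refs)
  expect_equal(absorbance(sp), epsilon(refs)[, "S"] * 8e-3)
  flat <- modelSpectrum(c(0, 0, 0, 0.05), refs)
  expect_equal(absorbance(flat), rep(0.05, length(wavelength(refs))))
  # linearity: equal-weight combination is the pointwise average basis sum
  avg <- modelSpectrum(c(0.5, 0, 0.5), refs)
  expect_equal(absorbance(avg),
               0.5 * epsilon(refs)[, "S"] * 8e-3 +
                 0.5 * epsilon(refs)[, "ES"] * 3.5e-3)
})

test_that("noise-free mixtures are recovered to numerical precision", {
  refs <- truthRefs()
  sp <- mixSpectrum(c(S = 10, ES = 1.5, P = 0), refs)
  r <- unmixSpectrum(sp, refs)
  expect_true(r@converged)
  expect_equal(unname(r@concentrations),
               c(10, 1.5, 0), tolerance = 1e-6)
  expect_lt(abs(r@baseline), 1e-8)
  # pure product reference recovery
  rp <- unmixSpectrum(mixSpectrum(c(S = 0, ES = 0, P = 5), refs), refs)
  expect_equal(unname(rp@concentrations), c(0, 0, 5), tolerance = 1e-6)
  # proportionality factors are amplitudes over reference concentrations
  expect_equal(unname(rp@metadata$proportionality["P"]), 1,
               tolerance = 1e-6)
})

test_that("all-zero spectra unmix to zero and scaling a spectrum scales the fit", {
  refs <- truthRefs()
  z <- unmixSpectrum(spectrum(wavelength(refs),
                              rep(0, length(wavelength(refs)))), refs)
  expect_equal(unname(z@concentrations), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(z@baseline, 0, tolerance = 1e-9)
  sp <- mixSpectrum(c(S = 4, ES = 2, P = 1), refs, p4 = 0.01,
                    p5 = 1e-11)
  k <- 2.5
  spk <- spectrum(wavelength(refs), k * absorbance(sp))
  r1 <- unmixSpectrum(sp, refs)
  rk <- unmixSpectrum(spk, refs)
  expect_equal(unname(rk@concentrations), k * unname(r1@concentrations),
               tolerance = 1e-6)
  expect_equal(rk@baseline, k * r1@baseline, tolerance = 1e-6)
  expect_equal(rk@scatter, k * r1@scatter, tolerance = 1e-6)
})

test_that("with fixed shifts the solver matches the linear least-squares oracle", {
  refs <- truthRefs()
  grid <- wavelength(refs)
  D <- cbind(epsilon(refs) * 1e-3, 1, (grid / 650)^3)
  cfg <- unmixConfig(nonnegConcentrations = FALSE)
  set.seed(7)
  for (i in 1:100) {
    theta <- c(runif(3, 0, 20), runif(1, -0.01, 0.01),
               runif(1, -1e-3, 1e-3))
    a <- as.numeric(D %*% theta)
    r <- unmixSpectrum(spectrum(grid, a), refs, cfg)
    oracle <- qr.coef(qr(D), a)  # independent direct linear solution
    got <- c(r@concentrations, r@baseline, r@scatter * 650^3)
    expect_equal(unname(got), unname(oracle), tolerance = 1e-8)
  }
})

test_that("Monte-Carlo replicates of a noisy mixture average to the truth", {
  refs <- truthRefs()
  truth <- c(S = 10, ES = 1.5, P = 2)
  base <- mixSpectrum(truth, refs)
  grid <- wavelength(refs)
  set.seed(11)
  recovered <- t(vapply(1:100, function(i) {
    sp <- spectrum(grid, absorbance(base) + rnorm(length(grid), sd = 0.002))
    unmixSpectrum(sp, refs)@concentrations
  }, numeric(3)))
  expect_equal(unname(colMeans(recovered)), unname(truth),
               tolerance = 0.02)
})

test_that("series unmixing tracks a binding time course and flags bad input", {
  refs <- truthRefs()
  p <- mechanismParams(kOn = 0.023 / 20, eTotal = 1, sTotal = 20)
  tr <- simulateMechanism(p, seq(0, 300, by = 20))
  cs <- unmixSeries(mixSeries(tr, refs), refs)
  expect_equal(speciesConcentration(cs, "ES"),
               speciesConcentration(tr, "ES"), tolerance = 1e-6)
  expect_equal(speciesConcentration(cs, "S"),
               speciesConcentration(tr, "S"), tolerance = 1e-6)
  expect_true(all(speciesConcentration(cs, "P") < 1e-6))
  expect_true(all(isConverged(cs)))
  expect_error(unmixSeries(list(), refs), "non-empty")
  # identical spectra give constant traces
  sp <- mixSpectrum(c(S = 5, ES = 1, P = 1), refs)
  csc <- unmixSeries(list(spectrum(wavelength(refs), absorbance(sp), time = 0),
                          spectrum(wavelength(refs), absorbance(sp), time = 5)),
                     refs)
  expect_equal(diff(speciesConcentration(csc, "S")), 0, tolerance = 1e-9)
})

test_that("warm starts do not change solutions on noise-free series", {
  refs <- truthRefs()
  p <- mechanismParams(kOn = 0.023 / 20, eTotal = 1, sTotal = 20)
  tr <- simulateMechanism(p, seq(0, 200, by = 40))
  spectra <- mixSeries(tr, refs)
  warm <- unmixSeries(spectra, refs)
  cold <- t(vapply(spectra, function(s)
    unmixSpectrum(s, refs)@concentrations, numeric(3)))
  expect_equal(unname(warm@conc), unname(cold), tolerance = 1e-8)
})

test_that("conservation check passes on closed systems and catches corruption", {
  refs <- truthRefs()
  p <- mechanismParams(kOn = 0.023 / 20, kCat = 4e-3, eTotal = 1,
                       sTotal = 20)
  tr <- simulateMechanism(p, seq(0, 600, by = 60))
  spectra <- mixSeries(tr, refs)
  cs <- unmixSeries(spectra, refs)
  rep1 <- conservationCheck(cs, 20, relTol = 1e-3)
  expect_true(rep1$pass)
  expect_lt(rep1$maxRelDeviation, 1e-6)
  # corrupt one spectrum: erase the product band although c_P > 0 in truth
  grid <- wavelength(refs)
  bad <- spectra
  i <- length(bad)
  a <- absorbance(bad[[i]])
  a[grid >= 660] <- 0
  bad[[i]] <- spectrum(grid, a, time = obsTime(tr)[i])
  csBad <- unmixSeries(bad, refs)
  expect_false(conservationCheck(csBad, 20, relTol = 1e-3)$pass)
  # single point equal to the expected total passes
  one <- unmixSeries(list(mixSpectrum(c(S = 20, ES = 0, P = 0), refs)), refs)
  expect_true(conservationCheck(one, 20, relTol = 1e-3)$pass)
})

test_that("free-shift mode still recovers an unshifted mixture", {
  refs <- truthRefs()
  sp <- mixSpectrum(c(S = 8, ES = 1, P = 0.5), refs)
  r <- unmixSpectrum(sp, refs, unmixConfig(fixShifts = FALSE, maxShift = 2))
  expect_equal(unname(r@concentrations), c(8, 1, 0.5), tolerance = 1e-3)
  expect_true(all(abs(r@shifts) <= 2))
})
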