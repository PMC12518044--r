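test_that("synthetic references hit the tabulated peak absorptivities exactly", {
  rs <- makeReferenceSet()
  eps <- epsilon(rs$refs)
  grid <- wavelength(rs$refs)
  expect_equal(unname(eps[grid == 651, "S"]), 23.4)
  expect_equal(unname(eps[grid == 633, "ES"]), 31.1)
  expect_equal(unname(eps[grid == 670, "P"]), 44.7)
  # noise-free raw S recording at 8 uM: A(651) = 23.4 * 0.008 = 0.1872 AU
  expect_equal(unname(absorbance(rs$raw$S)[grid == 651]), 0.1872)
})

test_that("zero-concentration references are flat zero", {
  rs <- makeReferenceSet(concentrations = c(S = 1e-12, ES = 3.5, P = 5))
  expect_lt(max(abs(absorbance(rs$raw$S))), 1e-12)
})

test_that("generation is byte-deterministic per seed and leaves the RNG alone", {
  scn <- canonicalScenarios()$fig5
  set.seed(123)
  before <- rnorm(1)
  g1 <- generateExperiment(scn, seed = 1, stage = 1)
  g2 <- generateExperiment(scn, seed = 1, stage = 1)
  g3 <- generateExperiment(scn, seed = 2, stage = 1)
  expect_identical(lapply(g1$spectra, absorbance),
                   lapply(g2$spectra, absorbance))
  expect_false(identical(absorbance(g1$spectra[[1]]),
                         absorbance(g3$spectra[[1]])))
  # same truth, different noise
  expect_identical(g1$truth@conc, g3$truth@conc)
  # caller RNG stream untouched by generation
  set.seed(123)
  expect_identical(before, rnorm(1))
})

test_that("the dead time suppresses early spectra in every stage", {
  scn <- canonicalScenarios()$fig5
  g1 <- generateExperiment(scn, seed = 1, stage = 1)
  expect_gte(min(obsTime(g1$truth)), 10)
  g2 <- generateExperiment(scn, seed = 1, stage = 2)
  expect_gte(min(obsTime(g2$truth)), 10)
})

test_that("noise-free generate -> unmix round-trips the truth", {
  scn <- canonicalScenarios(noise = list(sd = 0, baselineOffset = 0,
                                         baselineDrift = 0,
                                         scatterCoeff = 0))$fig5
  gen <- generateExperiment(scn, seed = 1, stage = 1)
  cs <- unmixSeries(gen$spectra, gen$refs)
  expect_equal(unname(cs@conc),
               unname(gen$truth@conc[, c("c_S", "c_ES", "c_P")]),
               tolerance = 1e-6)
})

test_that("baseline, drift and scatter terms are absorbed by the fit", {
  scn <- canonicalScenarios(noise = list(sd = 0))$fig5
  gen <- generateExperiment(scn, seed = 1, stage = 1)
  cs <- unmixSeries(gen$spectra, gen$refs)
  expect_lt(max(abs(speciesConcentration(cs, "ES") -
                      speciesConcentration(gen$truth, "ES"))), 1e-4)
})

test_that("recovered-parameter scatter grows with the noise level", {
  ks <- vapply(c(0.001, 0.004, 0.016), function(sdLevel) {
    scn <- canonicalScenarios(noise = list(sd = sdLevel))$fig5
    kk <- vapply(1:6, function(seed) {
      gen <- generateExperiment(scn, seed = seed, stage = 1)
      cs <- applyDeadTime(unmixSeries(gen$spectra, gen$refs), 10)
      coef(fitOnePhase(obsTime(cs), speciesConcentration(cs, "ES")))[["k"]]
    }, numeric(1))
    sd(kk)
  }, numeric(1))
  expect_true(all(diff(ks) > 0))
})

test_that("scenario presets encode the stated study conditions", {
  scns <- canonicalScenarios()
  # fig5: no catalysis without donor; 0.5 uM BchNB -> 1 uM of sites
  st1 <- scns$fig5@stages[[1]]
  expect_true(all(vapply(st1$params@pools, `[[`, numeric(1), "kCat") == 0))
  expect_equal(st1$params@eTotal, 1)
  expect_equal(unname(st1$inject["S"]), 20)
  # fig7: 20 uM Pchlide over 4 uM of sites (2 uM BchNB)
  st7 <- scns$fig7@stages[[1]]
  expect_equal(st7$params@eTotal, 4)
  expect_equal(unname(st7$inject["S"]), 20)
  # preset contract: the OBSERVED (fitted) binding constant of the
  # noise-free trajectory equals the reported value
  tr <- simulateEventSequence(list(st1))
  keep <- obsTime(tr) >= 10
  kObs <- coef(fitOnePhase(obsTime(tr)[keep],
                           speciesConcentration(tr, "ES")[keep]))[["k"]]
  expect_equal(kObs, 23e-3, tolerance = 1e-4)
  # and stays close to the depletion-free mapping k_on = k_obs / S_total
  expect_equal(st1$params@kOn * 20, 23e-3, tolerance = 0.1)
})
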