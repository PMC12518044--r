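test_that("smoothing with factor zero is the identity and recovers a noisy band", {
  grid <- 600:700
  band <- gaussBand(grid)
  set.seed(42)
  noisy <- spectrum(grid, band + rnorm(length(grid), sd = 0.002))
  expect_identical(absorbance(smoothReference(noisy, smoothing = 0)),
                   absorbance(noisy))
  sm <- smoothReference(noisy)
  expect_lt(max(abs(absorbance(sm) - band)), 0.004)
  # no systematic trend: mean residual vs the raw data within the noise level
  expect_lt(abs(mean(absorbance(sm) - absorbance(noisy))),
            3 * 0.002 / sqrt(length(grid)))
})

test_that("smoothing rejects too-few points and non-finite absorbance", {
  expect_error(smoothReference(spectrum(1:5, rep(0.1, 5))),
               "at least 20 points")
  expect_error(spectrum(600:650, c(NaN, rep(0.1, 50))), "finite")
})

test_that("Beer-Lambert conversion reproduces the tabulated peak absorptivities", {
  # A = eps * c[mM] * l: 23.4 * 0.008 = 0.1872 AU at 651 nm for 8 uM S
  sp <- spectrum(c(650, 651, 652), c(0.18, 0.1872, 0.18))
  expect_equal(toEpsilon(sp, concentration = 8)[2], 23.4)
  # product at 5 uM: 44.7 * 0.005 = 0.2235 AU
  spP <- spectrum(c(669, 670, 671), c(0.22, 0.2235, 0.22))
  expect_equal(toEpsilon(spP, concentration = 5)[2], 44.7)
  expect_equal(toEpsilon(spectrum(600:650, rep(0, 51)), 8),
               rep(0, 51))
  expect_error(toEpsilon(sp, concentration = 0), "positive")
})

test_that("Beer-Lambert conversion is scale invariant and round-trips", {
  grid <- 600:700
  a <- gaussBand(grid)
  sp <- spectrum(grid, a)
  spk <- spectrum(grid, 3 * a)
  expect_equal(toEpsilon(sp, 8), toEpsilon(spk, 24))
  eps <- toEpsilon(sp, 8)
  expect_equal(eps * 8e-3 * 1, a)
})

test_that("reference spectra record peak wavelength and absorptivity", {
  grid <- 600:700
  raw <- spectrum(grid, gaussBand(grid))
  ref <- referenceSpectrum("S", raw, concentration = 8, smoothing = 0)
  expect_equal(ref@peakWavelength, 651)
  expect_equal(ref@peakEpsilon, 23.4, tolerance = 1e-6)
})

test_that("ES calibration recovers an injected absorptivity error", {
  refs <- truthRefs()
  p <- mechanismParams(kOn = 0.023 / 20, eTotal = 1, sTotal = 20)
  tr <- simulateMechanism(p, seq(0, 600, by = 30))
  # truth: ES absorbs 25% stronger than the reference set believes
  biased <- epsilon(refs)
  biased[, "ES"] <- biased[, "ES"] * 1.25
  grid <- wavelength(refs)
  spectra <- lapply(seq_along(obsTime(tr)), function(i) {
    cc <- c(speciesConcentration(tr, "S")[i],
            speciesConcentration(tr, "ES")[i],
            speciesConcentration(tr, "P")[i])
    spectrum(grid, as.numeric(biased %*% (cc * 1e-3)),
             time = obsTime(tr)[i])
  })
  cal <- calibrateEsEpsilon(spectra, refs, totalPchlide = 20)
  expect_equal(cal$alpha, 1.25, tolerance = 1e-3)
  expect_equal(cal$meanTotal, 20, tolerance = 1e-3)
  # idempotence: recalibrating the calibrated set changes nothing
  cal2 <- calibrateEsEpsilon(spectra, cal$refs, totalPchlide = 20)
  expect_equal(cal2$alpha, 1, tolerance = 1e-3)
  # self-consistency: truth-matched references need no correction
  spectraOK <- mixSeries(tr, refs)
  expect_equal(calibrateEsEpsilon(spectraOK, refs, 20)$alpha, 1,
               tolerance = 1e-3)
})

test_that("ES calibration requires a long enough series", {
  refs <- truthRefs()
  sp <- mixSpectrum(c(S = 10, ES = 1, P = 0), refs)
  expect_error(calibrateEsEpsilon(list(sp, sp, sp), refs, 11),
               "at least 10")
})

test_that("resampling interpolates linearly and refuses extrapolation", {
  sp <- spectrum(seq(600, 700, by = 2), seq(0, 1, length.out = 51))
  expect_equal(absorbance(resampleSpectrum(sp, seq(600, 700, by = 2))),
               absorbance(sp))
  # exact on a linear segment
  fine <- resampleSpectrum(sp, seq(600, 700, by = 1))
  expect_equal(absorbance(fine), seq(0, 1, length.out = 101))
  expect_error(resampleSpectrum(sp, 599:700), "extends beyond")
})

test_that("reference set CSV round-trips with metadata", {
  refs <- truthRefs()
  path <- withr::local_tempfile(fileext = ".csv")
  writeReferenceSet(refs, path)
  back <- readReferenceSet(path)
  expect_equal(epsilon(back), epsilon(refs), tolerance = 1e-12)
  expect_equal(refConcentration(back), refConcentration(refs))
  expect_equal(analysisWindow(back), analysisWindow(refs))
})

test_that("raw reference CSV + sidecar reads into a calibrated reference", {
  dir <- withr::local_tempdir()
  grid <- 600:700
  csv <- file.path(dir, "refS.csv")
  utils::write.csv(data.frame(wavelength_nm = grid,
                              absorbance = gaussBand(grid)),
                   csv, row.names = FALSE)
  yaml::write_yaml(list(species = "S", concentration_uM = 8,
                        path_length_cm = 1),
                   file.path(dir, "refS.yaml"))
  ref <- readReferenceSpectrum(csv, smoothing = 0)
  expect_s4_class(ref, "ReferenceSpectrum")
  expect_equal(ref@peakEpsilon, 23.4, tolerance = 1e-6)
})
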