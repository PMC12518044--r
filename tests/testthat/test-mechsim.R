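test_that("pseudo-first-order binding matches the exponential closed form", {
  # S >> E: ES(t) = E_total (1 - exp(-k_on S_total t)) while S barely depletes
  p <- mechanismParams(kOn = 0.023 / 20, eTotal = 0.3, sTotal = 20)
  tg <- seq(0, 300, by = 5)
  tr <- simulateMechanism(p, tg)
  expected <- 0.3 * (1 - exp(-0.023 * tg))
  es <- speciesConcentration(tr, "ES")
  expect_lt(max(abs(es - expected)) / 0.3, 0.01)
  s <- speciesConcentration(tr, "S")
  expect_lt((20 - min(s)) / 20, 0.02)
  expect_equal(pseudoFirstOrderKobs(p), 0.023)
  expect_equal(pseudoFirstOrderKobs(
    mechanismParams(kOn = 0, kOff = 0.01, sTotal = 5)), 0.01)
})

test_that("all-zero rate constants give a constant trajectory", {
  p <- mechanismParams(eTotal = 1, sTotal = 20)
  tr <- simulateMechanism(p, seq(0, 100, by = 10))
  expect_equal(speciesConcentration(tr, "S"), rep(20, 11))
  expect_equal(speciesConcentration(tr, "ES"), rep(0, 11))
})

test_that("mass and site conservation hold to integrator tolerance", {
  p <- mechanismParams(kOn = 0.01, kOff = 0.002, eTotal = 2, sTotal = 20,
                       pools = list(list(fraction = 0.5, kCat = 0.01),
                                    list(fraction = 0.5, kCat = 0.001)))
  tr <- simulateMechanism(p, seq(0, 1000, by = 10))
  expect_lt(max(abs(totalConcentration(tr) - 20)) / 20, 1e-9)
  sites <- speciesConcentration(tr, "ES") + speciesConcentration(tr, "Efree")
  expect_lt(max(abs(sites - 2)) / 2, 1e-9)
})

test_that("product is nondecreasing and donor-free ES formation is monotone", {
  p <- mechanismParams(kOn = 0.005, kOff = 0.001, kCat = 0.01,
                       eTotal = 1, sTotal = 20)
  tr <- simulateMechanism(p, seq(0, 800, by = 5))
  expect_true(all(diff(speciesConcentration(tr, "P")) >= -1e-12))
  p0 <- mechanismParams(kOn = 0.005, kOff = 0.001, eTotal = 1, sTotal = 20)
  tr0 <- simulateMechanism(p0, seq(0, 800, by = 5))
  expect_true(all(diff(speciesConcentration(tr0, "ES")) >= -1e-9))
})

test_that("binding equilibrium matches the quadratic closed form for Kd", {
  kOn <- 0.01; kOff <- 0.05   # Kd = 5 uM
  E <- 2; S <- 10
  p <- mechanismParams(kOn = kOn, kOff = kOff, eTotal = E, sTotal = S)
  tr <- simulateMechanism(p, c(0, 10^(1:5)))
  Kd <- kOff / kOn
  b <- E + S + Kd
  esEq <- (b - sqrt(b^2 - 4 * E * S)) / 2
  es <- speciesConcentration(tr, "ES")
  expect_equal(es[length(es)], esEq, tolerance = 1e-6)
})

test_that("the rapid-turnover limit reduces to encounter-limited product formation", {
  # k_cat -> infinity: ES never accumulates, P forms at the encounter rate,
  # i.e. like the one-step reduced model dS/dt = -k_on * E * S
  p <- mechanismParams(kOn = 1, kCat = 1e6, eTotal = 0.1, sTotal = 10)
  tg <- seq(0, 50, by = 0.5)
  tr <- simulateMechanism(p, tg)
  expect_lt(max(speciesConcentration(tr, "ES")), 1e-3)
  reduced <- 10 * (1 - exp(-1 * 0.1 * tg))   # E stays ~free at 0.1 uM
  expect_lt(max(abs(speciesConcentration(tr, "P") - reduced)) / 10, 0.02)
})

test_that("two ES pools under saturation give exactly the two-phase form", {
  # pre-loaded sites, no rebinding: P(t) = sum of independent exponentials
  stages <- list(list(
    duration = 3000, sampleInterval = 5,
    params = mechanismParams(kOn = 0, eTotal = 1, sTotal = 0,
                             recycle = FALSE,
                             pools = list(list(fraction = 0.5, kCat = 0.004),
                                          list(fraction = 0.5,
                                               kCat = 0.0006))),
    inject = c(ES = 1, S = 19)))
  tr <- simulateEventSequence(stages)
  fit <- fitTwoPhase(obsTime(tr), speciesConcentration(tr, "P"))
  p <- coef(fit)
  expect_equal(p[["k_fast"]], 0.004, tolerance = 1e-4)
  expect_equal(p[["k_slow"]], 0.0006, tolerance = 1e-4)
  expect_equal(p[["span_fast"]], 0.5, tolerance = 1e-3)
  expect_equal(p[["span_slow"]], 0.5, tolerance = 1e-3)
})

test_that("sequential two-site binding yields biphasic ES formation", {
  p <- mechanismParams(siteModel = "two_site", kOn1 = 0.018 / 20,
                       kOn2 = 0.0022 / 20, eTotal = 4, sTotal = 20)
  tr <- simulateMechanism(p, seq(0, 1800, by = 5))
  es <- speciesConcentration(tr, "ES")
  expect_true(all(diff(es) > -1e-9))
  expect_equal(es[length(es)], 4, tolerance = 0.05)
  fit2 <- fitTwoPhase(obsTime(tr)[-1], es[-1])
  fit1 <- fitOnePhase(obsTime(tr)[-1], es[-1])
  expect_identical(selectModel(fit1, fit2)$model, "two_phase")
})

test_that("event sequences are continuous, inject cleanly, and concatenate", {
  p <- mechanismParams(kOn = 0.001, eTotal = 1, sTotal = 0)
  # injection appears as a step in the injected species only
  tr <- simulateEventSequence(list(list(duration = 10, sampleInterval = 1,
                                        params = p, inject = c(S = 20))))
  expect_equal(speciesConcentration(tr, "S")[1], 20)
  expect_equal(speciesConcentration(tr, "P")[1], 0)
  # no catalysis without donor: P stays 0 through a donor-free stage
  scns <- canonicalScenarios()
  st1 <- scns$fig5@stages[[1]]
  trS <- simulateEventSequence(list(st1))
  expect_true(all(speciesConcentration(trS, "P") < 1e-12))
  # two identical stages equal one run of double duration
  pp <- mechanismParams(kOn = 0.002, kOff = 0.001, eTotal = 1, sTotal = 0)
  two <- simulateEventSequence(list(
    list(duration = 100, sampleInterval = 5, params = pp,
         inject = c(S = 10)),
    list(duration = 100, sampleInterval = 5, params = pp)))
  one <- simulateEventSequence(list(
    list(duration = 200, sampleInterval = 5, params = pp,
         inject = c(S = 10))))
  expect_equal(obsTime(two), obsTime(one))
  expect_equal(two@conc, one@conc, tolerance = 1e-8)
  expect_error(simulateEventSequence(list(list(duration = 10,
                                               sampleInterval = 1,
                                               params = pp,
                                               inject = c(S = -1)))),
               "negative")
})
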