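test_that("one-phase association recovers its own closed form exactly", {
  t <- seq(5, 600, by = 5)
  y <- 0 + (1.5 - 0) * (1 - exp(-0.023 * t))
  fit <- fitOnePhase(t, y)
  expect_equal(unname(coef(fit)), c(0, 1.5, 0.023), tolerance = 1e-8)
  expect_equal(fit@rSquared, 1, tolerance = 1e-12)
  expect_length(fitFlags(fit), 0)
})

test_that("constant traces are flagged unidentifiable, not fitted", {
  t <- seq(0, 100, by = 5)
  fit <- fitOnePhase(t, rep(1.3, length(t)))
  expect_true("unidentifiable" %in% fitFlags(fit))
  expect_true(is.na(coef(fit)["k"]))
  fit2 <- fitTwoPhase(t, rep(1.3, length(t)))
  expect_true("unidentifiable" %in% fitFlags(fit2))
})

test_that("two-phase association recovers its own closed form and orders rates", {
  t <- seq(5, 3000, by = 5)
  y <- 0.1 + 0.8 * (1 - exp(-0.004 * t)) + 0.8 * (1 - exp(-0.0006 * t))
  fit <- fitTwoPhase(t, y)
  p <- coef(fit)
  expect_equal(unname(p[c("y0", "span_fast", "k_fast", "span_slow",
                          "k_slow")]),
               c(0.1, 0.8, 0.004, 0.8, 0.0006), tolerance = 1e-6)
  expect_gte(p[["k_fast"]], p[["k_slow"]])
})

test_that("one-phase data fed to the two-phase model is flagged as such", {
  t <- seq(5, 600, by = 5)
  y <- 1.5 * (1 - exp(-0.023 * t))
  fit <- fitTwoPhase(t, y)
  p <- coef(fit)
  collapsed <- any(c("span_collapse", "k_equal") %in% fitFlags(fit)) ||
    abs(p[["k_fast"]] - p[["k_slow"]]) < 1e-3 * p[["k_fast"]]
  expect_true(collapsed)
})

test_that("two-phase nests one-phase: equal rates reproduce the single exponential", {
  t <- seq(0, 500, by = 10)
  one <- fitOnePhase(t, 2 * (1 - exp(-0.01 * t)) + 0.2)
  p1 <- coef(one)
  two <- new("KineticFit", model = "two_phase",
             params = c(y0 = p1[["y0"]],
                        span_fast = 0.6 * (p1[["plateau"]] - p1[["y0"]]),
                        k_fast = p1[["k"]],
                        span_slow = 0.4 * (p1[["plateau"]] - p1[["y0"]]),
                        k_slow = p1[["k"]]),
             stderr = rep(NA_real_, 5), aicc = NA_real_,
             rSquared = NA_real_, nPoints = length(t),
             data = list(t = t, y = predict(one)))
  expect_equal(predict(two, t), predict(one, t), tolerance = 1e-10)
})

test_that("fitted association curves are nondecreasing for positive spans", {
  t <- seq(5, 1500, by = 5)
  set.seed(3)
  y <- 0.7 * (1 - exp(-0.012 * t)) + 0.5 * (1 - exp(-0.0012 * t)) +
    rnorm(length(t), sd = 0.02)
  fit <- fitTwoPhase(t, y)
  expect_true(all(diff(predict(fit, seq(0, 2000, by = 1))) >= 0))
})

test_that("initial rates convert between uM/s and nmol/s via the assay volume", {
  t <- 0:10
  fit <- fitInitialRate(t, 0.8 * t, window = 5, volumeML = 2)
  expect_equal(coef(fit)[["rate"]], 0.8, tolerance = 1e-12)
  expect_equal(coef(fit)[["rate_nmol_s"]], 1.6, tolerance = 1e-12)
  flat <- fitInitialRate(t, rep(2, 11), window = 10)
  expect_equal(coef(flat)[["rate"]], 0, tolerance = 1e-12)
  expect_error(fitInitialRate(c(0, 1), c(0, 1), window = 5),
               "at least 4")
})

test_that("model selection picks by AICc and breaks ties toward simplicity", {
  t <- seq(5, 2000, by = 5)
  set.seed(5)
  noise <- rnorm(length(t), sd = 0.01)
  # strongly biphasic data: rate ratio 10, equal spans
  yb <- 1 * (1 - exp(-0.01 * t)) + 1 * (1 - exp(-0.001 * t)) + noise
  sel <- selectModel(fitOnePhase(t, yb), fitTwoPhase(t, yb))
  expect_identical(sel$model, "two_phase")
  # pure one-phase data
  y1 <- 2 * (1 - exp(-0.005 * t)) + noise
  sel1 <- selectModel(fitOnePhase(t, y1), fitTwoPhase(t, y1))
  expect_identical(sel1$model, "one_phase")
  # forced tie: identical AICc favours the simpler model
  f1 <- fitOnePhase(t, y1)
  f2 <- fitTwoPhase(t, y1)
  f2@aicc <- f1@aicc
  expect_identical(selectModel(f1, f2)$model, "one_phase")
  # mismatched data is an input error
  f3 <- fitOnePhase(t + 1, 2 * (1 - exp(-0.005 * (t + 1))))
  expect_error(selectModel(f3, f2), "identical data")
})

test_that("dead-time truncation drops early points and degenerates safely", {
  p <- mechanismParams(kOn = 0.023 / 20, eTotal = 1, sTotal = 20)
  tr <- simulateMechanism(p, seq(0, 600, by = 5))
  spectra <- mixSeries(tr)
  cs <- unmixSeries(spectra, truthRefs())
  expect_identical(applyDeadTime(cs, 0), cs)
  trunc <- applyDeadTime(cs, 10)
  expect_equal(min(obsTime(trunc)), 10)
  expect_equal(trunc@metadata$truncation$nDropped, 2)
  expect_error(applyDeadTime(cs, 1000), "every point")
})

test_that("10 s censoring biases a 0.023/s rate by less than 5%", {
  t <- seq(0, 600, by = 5)
  y <- 1.0 * (1 - exp(-0.023 * t))
  keep <- t >= 10
  fit <- fitOnePhase(t[keep], y[keep])
  expect_lt(abs(coef(fit)[["k"]] - 0.023) / 0.023, 0.05)
})

test_that("standard errors calibrate against the replicate spread of k", {
  t <- seq(5, 600, by = 5)
  truth <- 1.5 * (1 - exp(-0.023 * t))
  set.seed(9)
  fits <- lapply(1:40, function(i)
    fitOnePhase(t, truth + rnorm(length(t), sd = 0.02)))
  ks <- vapply(fits, function(f) coef(f)[["k"]], numeric(1))
  ses <- vapply(fits, function(f) fitStdErr(f)[["k"]], numeric(1))
  # reported SE within a factor ~2 of the observed spread
  expect_gt(median(ses), sd(ks) / 2)
  expect_lt(median(ses), sd(ks) * 2)
})
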