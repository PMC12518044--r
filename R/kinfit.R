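#' @include AllClasses.R AllGenerics.R constants.R
NULL

# ---- internal helpers -------------------------------------------------------

# AICc with K = nPar + 1 (the residual variance counts as a parameter, the
# convention of common graphing software, so model comparisons match it).
.aicc <- function(rss, n, nPar) {
  k <- nPar + 1
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

.rsq <- function(y, resid) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(NA_real_)
  1 - sum(resid^2) / tss
}

# Standard errors in the reported parameterization from the solver's local
# curvature, via the delta method (grad = d reported / d internal). The
# solver's hessian approximates 2 J'J for a residual objective, so the
# covariance of the internal parameters is 2 sigma^2 H^-1.
.stderrFromFit <- function(fit, grad) {
  n <- length(fit$fvec)
  p <- length(fit$par)
  rss <- sum(fit$fvec^2)
  sigma2 <- rss / max(n - p, 1)
  covInt <- tryCatch(2 * sigma2 * solve(fit$hessian),
                     error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(grad %*% covInt %*% t(grad)), 0))
  se
}

.lmMultiStart <- function(fn, starts, lower = NULL, upper = NULL,
                          control = minpack.lm::nls.lm.control(
                            ftol = 1e-12, ptol = 1e-12, maxiter = 500)) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = fn,
                         lower = lower %||% rep(-Inf, length(s)),
                         upper = upper %||% rep(Inf, length(s)),
                         control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.checkTimeSeries <- function(t, y, minPoints, what) {
  if (length(t) != length(y))
    .stopInvalid("t and y must have equal length")
  if (any(!is.finite(t)) || any(!is.finite(y)))
    .stopInvalid("t and y must be finite")
  if (any(diff(t) <= 0))
    .stopInvalid("t must be strictly increasing")
  if (length(t) < minPoints)
    .stopInvalid(what, " needs at least ", minPoints, " points (got ",
                 length(t), ")")
}

# ---- models -----------------------------------------------------------------

#' Plateau followed by one-phase association fit
#'
#' Fits \eqn{y(t) = y_0 + (plateau - y_0)(1 - e^{-kt})} by unweighted
#' least squares (optional weights supported). The rate constant is fitted on
#' a log scale so \eqn{k > 0} holds by construction; standard errors are
#' transformed back by the delta method. \code{y0} is a free parameter
#' because instrument dead time makes the first observed point differ from
#' the true start of the reaction.
#'
#' @param t numeric, times (s), strictly increasing, at least 6 points (after
#'   any dead-time truncation, which is the caller's responsibility via
#'   [applyDeadTime()]).
#' @param y numeric, concentrations (uM).
#' @param weights optional numeric weights (inverse-variance style).
#' @return A [KineticFit-class] with parameters \code{y0}, \code{plateau},
#'   \code{k}. A constant trace gives an unidentifiable rate and is returned
#'   flagged (\code{"unidentifiable"}) rather than silently fitted.
#' @export
#' @examples
#' t <- seq(5, 600, by = 5)
#' y <- 1.5 * (1 - exp(-0.023 * t))
#' coef(fitOnePhase(t, y))
fitOnePhase <- function(t, y, weights = NULL) {
  .checkTimeSeries(t, y, 6, "one-phase fit")
  w <- sqrt(weights %||% rep(1, length(y)))
  span <- diff(range(y))
  if (span < 1e-12 * max(abs(y), 1)) {
    return(new("KineticFit", model = "one_phase",
               params = c(y0 = y[1], plateau = y[1], k = NA_real_),
               stderr = c(y0 = NA_real_, plateau = NA_real_, k = NA_real_),
               aicc = Inf, rSquared = NA_real_, nPoints = length(t),
               flags = c("unidentifiable", "constant_input"),
               data = list(t = t, y = y)))
  }
  model <- function(p) p[1] + (p[2] - p[1]) * (1 - exp(-exp(p[3]) * t))
  fn <- function(p) w * (model(p) - y)
  kGuess <- 2 / stats::median(t)
  starts <- lapply(c(0.1, 1, 10), function(m)
    c(y[1], y[length(y)], log(kGuess * m)))
  fit <- .lmMultiStart(fn, starts)
  if (is.null(fit)) .stopFitFailure("one-phase fit did not converge")
  p <- fit$par
  k <- exp(p[3])
  grad <- diag(3); grad[3, 3] <- k  # d(k)/d(log k) = k
  se <- .stderrFromFit(fit, grad)
  flags <- character()
  if (!fit$info %in% 1:3) flags <- c(flags, "not_converged")
  if (k > 10 / (t[2] - t[1])) flags <- c(flags, "rate_above_sampling")
  if (k < 0.1 / diff(range(t))) flags <- c(flags, "rate_below_window")
  rss <- sum(fit$fvec^2)
  new("KineticFit", model = "one_phase",
      params = c(y0 = p[1], plateau = p[2], k = k),
      stderr = c(y0 = se[1], plateau = se[2], k = se[3]),
      aicc = .aicc(rss, length(t), 3),
      rSquared = .rsq(y, model(p) - y),
      nPoints = length(t), flags = flags,
      data = list(t = t, y = y))
}

#' Two-phase association fit
#'
#' Fits \eqn{y(t) = y_0 + span_f (1 - e^{-k_f t}) + span_s (1 - e^{-k_s t})}.
#' To remove label switching, the internal parameterization is
#' \eqn{(y_0, span_f, span_s, \log k_s, \log(k_f / k_s))} with the log-ratio
#' bounded at 0, so \eqn{k_{fast} \ge k_{slow}} always holds.
#'
#' @inheritParams fitOnePhase
#' @return A [KineticFit-class] with parameters \code{y0}, \code{span_fast},
#'   \code{k_fast}, \code{span_slow}, \code{k_slow}. A collapsed span
#'   (either span below 1e-6 of the total) or \eqn{k_{fast} \approx k_{slow}}
#'   is flagged (\code{"span_collapse"}, \code{"k_equal"}): the data are then
#'   effectively one-phase.
#' @export
fitTwoPhase <- function(t, y, weights = NULL) {
  .checkTimeSeries(t, y, 8, "two-phase fit")
  w <- sqrt(weights %||% rep(1, length(y)))
  span <- diff(range(y))
  if (span < 1e-12 * max(abs(y), 1)) {
    return(new("KineticFit", model = "two_phase",
               params = c(y0 = y[1], span_fast = 0, k_fast = NA_real_,
                          span_slow = 0, k_slow = NA_real_),
               stderr = rep(NA_real_, 5),
               aicc = Inf, rSquared = NA_real_, nPoints = length(t),
               flags = c("unidentifiable", "constant_input"),
               data = list(t = t, y = y)))
  }
  model <- function(p) {
    ks <- exp(p[4]); kf <- ks * exp(p[5])
    p[1] + p[2] * (1 - exp(-kf * t)) + p[3] * (1 - exp(-ks * t))
  }
  fn <- function(p) w * (model(p) - y)
  one <- tryCatch(fitOnePhase(t, y, weights), error = function(e) NULL)
  k1 <- if (!is.null(one) && is.finite(coef(one)["k"])) coef(one)[["k"]]
        else 2 / stats::median(t)
  sp1 <- if (!is.null(one)) coef(one)[["plateau"]] - coef(one)[["y0"]]
         else span
  starts <- list(
    c(y[1], sp1 / 2, sp1 / 2, log(k1 / 5), log(25)),
    c(y[1], sp1 / 2, sp1 / 2, log(k1 / 2), log(4)),
    c(y[1], sp1 * 0.8, sp1 * 0.2, log(k1 / 10), log(100)))
  lower <- c(-Inf, 0, 0, -Inf, 0)
  fit <- .lmMultiStart(fn, starts, lower = lower)
  if (is.null(fit)) .stopFitFailure("two-phase fit did not converge")
  p <- fit$par
  ks <- exp(p[4]); kf <- ks * exp(p[5])
  # reported params: (y0, span_fast, k_fast, span_slow, k_slow)
  grad <- matrix(0, 5, 5)
  grad[1, 1] <- 1; grad[2, 2] <- 1; grad[4, 3] <- 1
  grad[3, 4] <- kf; grad[3, 5] <- kf   # k_fast = exp(p4 + p5)
  grad[5, 4] <- ks                     # k_slow = exp(p4)
  se <- .stderrFromFit(fit, grad)
  flags <- character()
  if (!fit$info %in% 1:3) flags <- c(flags, "not_converged")
  tot <- p[2] + p[3]
  if (tot > 0 && (p[2] < 1e-6 * tot || p[3] < 1e-6 * tot))
    flags <- c(flags, "span_collapse")
  if (p[5] < 1e-3) flags <- c(flags, "k_equal")
  if (length(flags)) flags <- c(flags, "consider_one_phase")
  rss <- sum(fit$fvec^2)
  new("KineticFit", model = "two_phase",
      params = c(y0 = p[1], span_fast = p[2], k_fast = kf,
                 span_slow = p[3], k_slow = ks),
      stderr = c(y0 = se[1], span_fast = se[2], k_fast = se[3],
                 span_slow = se[4], k_slow = se[5]),
      aicc = .aicc(rss, length(t), 5),
      rSquared = .rsq(y, model(p) - y),
      nPoints = length(t), flags = flags,
      data = list(t = t, y = y))
}

#' Initial-rate (linear) fit over an early time window
#'
#' Ordinary least-squares line through the points with
#' \eqn{t \le t_{min} + window}. The slope is reported in uM/s and, given the
#' assay volume, converted to an absolute rate in nmol/s
#' (uM x mL = nmol).
#'
#' @param t,y as in [fitOnePhase()]; at least 4 points must fall in the
#'   window.
#' @param window numeric(1), window length in seconds from the first point.
#' @param volumeML numeric(1), assay volume in mL (default 2, the in-situ
#'   cuvette volume).
#' @return A [KineticFit-class] (model \code{"linear"}) with parameters
#'   \code{intercept} (uM), \code{rate} (uM/s) and \code{rate_nmol_s}
#'   (nmol/s).
#' @export
fitInitialRate <- function(t, y, window, volumeML = 2) {
  if (length(t) != length(y)) .stopInvalid("t and y must have equal length")
  keep <- t <= t[1] + window
  if (sum(keep) < 4)
    .stopInvalid("initial-rate window must contain at least 4 points (got ",
                 sum(keep), ")")
  tw <- t[keep]; yw <- y[keep]
  fit <- stats::lm(yw ~ tw)
  co <- stats::coef(fit)
  # suppressed: summary.lm warns on exact (zero-residual) data
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  resid <- stats::resid(fit)
  rate <- unname(co[2])
  new("KineticFit", model = "linear",
      params = c(intercept = unname(co[1]), rate = rate,
                 rate_nmol_s = rate * volumeML),
      stderr = c(intercept = unname(se[1]), rate = unname(se[2]),
                 rate_nmol_s = unname(se[2]) * volumeML),
      aicc = .aicc(sum(resid^2), length(tw), 2),
      rSquared = .rsq(yw, resid),
      nPoints = length(tw), flags = character(),
      data = list(t = tw, y = yw))
}

#' Choose between two kinetic fits by AICc
#'
#' Returns the model with the lower small-sample Akaike score; a difference
#' of less than 2 is treated as a tie and resolved in favour of the model
#' with fewer parameters (parsimony).
#'
#' @param fit1,fit2 [KineticFit-class] objects fitted to identical data.
#' @return list with \code{model} (name), \code{chosen} (the winning
#'   [KineticFit-class]), \code{deltaAICc} (AICc of the more complex minus
#'   the simpler model) and \code{tie}.
#' @export
selectModel <- function(fit1, fit2) {
  if (!isTRUE(all.equal(fit1@data$t, fit2@data$t)) ||
      !isTRUE(all.equal(fit1@data$y, fit2@data$y)))
    .stopInvalid("model selection requires fits on identical data")
  nPar <- c(length(fit1@params), length(fit2@params))
  simpler <- which.min(nPar)
  d <- aicc(fit1) - aicc(fit2)   # >0 favours fit2
  if (abs(d) < 2) {
    chosen <- if (simpler == 1) fit1 else fit2
    tie <- TRUE
  } else {
    chosen <- if (d < 0) fit1 else fit2
    tie <- FALSE
  }
  complexFit <- if (simpler == 1) fit2 else fit1
  simpleFit <- if (simpler == 1) fit1 else fit2
  list(model = chosen@model, chosen = chosen,
       deltaAICc = aicc(complexFit) - aicc(simpleFit), tie = tie)
}

#' @describeIn applyDeadTime Drop all points with \code{t < dead}; the
#'   truncation is recorded in \code{metadata$truncation}. Removing every
#'   point is an error.
setMethod("applyDeadTime", "ConcentrationSeries", function(series, dead = 10,
                                                           ...) {
  if (dead < 0) .stopInvalid("dead time must be >= 0")
  if (dead == 0) return(series)
  keep <- series@time >= dead
  if (!any(keep))
    .stopInvalid("dead time (", dead, " s) removes every point of the series")
  md <- series@metadata
  md$truncation <- list(tDead = dead, nDropped = sum(!keep))
  new("ConcentrationSeries", time = series@time[keep],
      conc = series@conc[keep, , drop = FALSE],
      residualRMS = series@residualRMS[keep],
      converged = series@converged[keep], metadata = md)
})

#' Predicted values of a kinetic fit
#'
#' @param object a [KineticFit-class].
#' @param t numeric, times at which to evaluate (defaults to the fitted
#'   times).
#' @param ... unused.
#' @return numeric, model predictions (uM).
#' @export
setMethod("predict", "KineticFit", function(object, t = NULL, ...) {
  if (is.null(t)) t <- object@data$t
  p <- object@params
  switch(object@model,
    one_phase = p[["y0"]] + (p[["plateau"]] - p[["y0"]]) *
      (1 - exp(-p[["k"]] * t)),
    two_phase = p[["y0"]] + p[["span_fast"]] * (1 - exp(-p[["k_fast"]] * t)) +
      p[["span_slow"]] * (1 - exp(-p[["k_slow"]] * t)),
    linear = p[["intercept"]] + p[["rate"]] * t,
    stop("unknown model"))
})
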