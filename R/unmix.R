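#' @include AllClasses.R AllGenerics.R constants.R references.R
NULL

#' Create an unmixing configuration
#'
#' @param fixShifts logical(1), pin the per-species wavelength shifts at 0 nm
#'   (default \code{TRUE}; shifts were not needed on the instruments this
#'   workflow targets).
#' @param scatterExponent integer(1), exponent of the \code{p5 lambda^e}
#'   baseline/turbidity term; 3 (default), -3 or -4.
#' @param nonnegConcentrations logical(1), constrain concentrations to be
#'   nonnegative (default \code{TRUE}); an unconstrained mode is available for
#'   diagnostics.
#' @param maxShift numeric(1), bound (nm) on each shift when shifts are free.
#' @param ftol,ptol numeric(1), solver tolerances.
#' @param maxIter integer(1), iteration cap.
#' @return An [UnmixConfig-class].
#' @export
unmixConfig <- function(fixShifts = TRUE, scatterExponent = 3,
                        nonnegConcentrations = TRUE, maxShift = 3,
                        ftol = 1e-10, ptol = 1e-12, maxIter = 500) {
  new("UnmixConfig", fixShifts = fixShifts,
      scatterExponent = scatterExponent,
      nonnegConcentrations = nonnegConcentrations, maxShift = maxShift,
      ftol = ftol, ptol = ptol, maxIter = as.numeric(maxIter))
}

# Window indices of a ReferenceSet grid.
.windowIndex <- function(refs) {
  which(refs@grid >= refs@window[1] - 1e-9 &
        refs@grid <= refs@window[2] + 1e-9)
}

# Design matrix on the analysis window, columns (S, ES, P, baseline, scatter),
# in concentration units: absorbance per uM for the species columns. The
# scatter column is scaled by 650^-e for conditioning; reported p5 undoes it.
.designMatrix <- function(refs, exponent, pathLength = 1) {
  idx <- .windowIndex(refs)
  lam <- refs@grid[idx]
  D <- cbind(refs@epsilon[idx, c("S", "ES", "P"), drop = FALSE] * 1e-3 *
               pathLength,
             baseline = 1,
             scatter = (lam / 650)^exponent)
  list(D = D, lambda = lam, idx = idx)
}

# Shifted reference lookup with edge clamping; flags out-of-range requests.
.shiftedRef <- function(grid, values, shift) {
  x <- grid - shift
  clipped <- any(x < min(grid) - 1e-9 | x > max(grid) + 1e-9)
  y <- stats::approx(grid, values, xout = pmin(pmax(x, min(grid)),
                                               max(grid)))$y
  list(y = y, clipped = clipped)
}

#' Evaluate the reference-spectrum mixture model
#'
#' The per-spectrum fitting function
#' \deqn{f(\lambda) = p_1 S_S(\lambda - p_6) + p_2 S_P(\lambda - p_7) +
#'   p_3 S_{ES}(\lambda - p_8) + p_4 + p_5 \lambda^e}
#' where \eqn{S_S, S_P, S_{ES}} are the smoothed reference absorbance spectra
#' at their known recording concentrations, \eqn{p_1..p_3} are proportionality
#' factors, \eqn{p_4} a flat baseline, \eqn{p_5} a scatter/turbidity
#' coefficient and \eqn{p_6..p_8} wavelength shifts (0 by default). Shift
#' arguments leaving the grid are clamped to the nearest grid value.
#'
#' @param params numeric, up to 8 values \code{p1..p8} (missing trailing
#'   entries are taken as 0).
#' @param refs a [ReferenceSet-class].
#' @param exponent integer(1), scatter exponent e (default 3).
#' @param pathLength numeric(1), cm.
#' @return A [Spectrum-class] evaluated on the analysis window.
#' @export
#' @examples
#' refs <- makeReferenceSet()$refs
#' sp <- modelSpectrum(c(1, 0, 0), refs)  # the S reference spectrum itself
modelSpectrum <- function(params, refs, exponent = 3, pathLength = 1) {
  p <- rep(0, 8)
  p[seq_along(params)] <- params
  idx <- .windowIndex(refs)
  lam <- refs@grid[idx]
  rc <- refs@refConcentration
  # reference absorbance spectra at recording concentrations, full grid
  refA <- sweep(refs@epsilon, 2, rc * 1e-3 * pathLength, `*`)
  sS <- .shiftedRef(refs@grid, refA[, "S"], p[6])$y[idx]
  sP <- .shiftedRef(refs@grid, refA[, "P"], p[7])$y[idx]
  sES <- .shiftedRef(refs@grid, refA[, "ES"], p[8])$y[idx]
  f <- p[1] * sS + p[2] * sP + p[3] * sES + p[4] + p[5] * lam^exponent
  spectrum(lam, f, pathLength = pathLength)
}

#' Decompose one spectrum into species concentrations
#'
#' Nonlinear least-squares fit (Levenberg-Marquardt) of the reference-spectrum
#' mixture model to an observed spectrum over the analysis window. With
#' shifts fixed (default) the model is linear in the remaining parameters and
#' the solver converges to the exact least-squares solution. Concentrations
#' are obtained from the fitted amplitudes via the known reference
#' concentrations (proportionality factor times recording concentration,
#' identical to amplitude over absorptivity).
#'
#' @param spec a [Spectrum-class] covering the analysis window.
#' @param refs a [ReferenceSet-class] (calibrated).
#' @param config an [UnmixConfig-class].
#' @param start optional numeric, warm-start parameter vector from a previous
#'   fit (as stored in the result metadata).
#' @return An [UnmixResult-class]. Non-convergence is flagged in
#'   \code{converged}, never silent.
#' @export
unmixSpectrum <- function(spec, refs, config = unmixConfig(), start = NULL) {
  if (!is(spec, "Spectrum")) .stopInvalid("spec must be a Spectrum")
  dm <- .designMatrix(refs, config@scatterExponent, spec@pathLength)
  sp <- if (identical(spec@wavelength, dm$lambda)) spec
        else resampleSpectrum(spec, dm$lambda)
  A <- sp@absorbance
  D <- dm$D
  # deterministic warm start: unconstrained linear pre-fit, negatives clipped
  theta0 <- tryCatch(unname(qr.coef(qr(D), A)),
                     error = function(e) rep(0, 5))
  theta0[is.na(theta0)] <- 0
  if (config@nonnegConcentrations) theta0[1:3] <- pmax(theta0[1:3], 0)
  if (!is.null(start)) theta0 <- start[seq_len(5)]
  lower <- c(if (config@nonnegConcentrations) c(0, 0, 0) else rep(-Inf, 3),
             -Inf, -Inf)
  ctrl <- minpack.lm::nls.lm.control(ftol = config@ftol, ptol = config@ptol,
                                     maxiter = config@maxIter)
  clippedShift <- FALSE
  if (config@fixShifts) {
    fit <- minpack.lm::nls.lm(
      par = theta0,
      fn = function(par) as.numeric(D %*% par - A),
      jac = function(par) D,
      lower = lower, control = ctrl)
    par <- unname(fit$par)
    shifts <- c(S = 0, ES = 0, P = 0)
  } else {
    rc <- refs@refConcentration
    refA <- sweep(refs@epsilon, 2, rc * 1e-3 * sp@pathLength, `*`)
    resfun <- function(par) {
      sS <- .shiftedRef(refs@grid, refA[, "S"], par[6])
      sP <- .shiftedRef(refs@grid, refA[, "P"], par[7])
      sES <- .shiftedRef(refs@grid, refA[, "ES"], par[8])
      clippedShift <<- clippedShift || sS$clipped || sP$clipped ||
        sES$clipped
      # concentration-unit columns: shifted reference spectra divided by
      # their recording concentrations (absorbance per uM)
      m <- cbind(sS$y[dm$idx] / rc["S"], sES$y[dm$idx] / rc["ES"],
                 sP$y[dm$idx] / rc["P"]) %*% par[1:3] +
        par[4] + par[5] * (dm$lambda / 650)^config@scatterExponent
      as.numeric(m - A)
    }
    fit <- minpack.lm::nls.lm(
      par = c(theta0, 0, 0, 0),
      fn = resfun,
      lower = c(lower, rep(-config@maxShift, 3)),
      upper = c(rep(Inf, 5), rep(config@maxShift, 3)),
      control = ctrl)
    par <- unname(fit$par[1:5])
    shifts <- c(S = unname(fit$par[6]), ES = unname(fit$par[7]),
                P = unname(fit$par[8]))
  }
  res <- as.numeric(D %*% par - A)  # residual at fixed-shift design
  if (!config@fixShifts) res <- fit$fvec
  conc <- c(S = par[1], ES = par[2], P = par[3])
  rc <- refs@refConcentration
  new("UnmixResult",
      concentrations = conc,
      baseline = par[4],
      scatter = par[5] / 650^config@scatterExponent,
      shifts = shifts,
      residualRMS = sqrt(mean(res^2)),
      converged = fit$info %in% 1:3,
      metadata = list(info = fit$info, niter = fit$niter,
                      par = fit$par,
                      proportionality = conc / rc[c("S", "ES", "P")],
                      shiftClipped = clippedShift))
}

#' Unmix a time-ordered series of spectra
#'
#' Runs [unmixSpectrum()] on each spectrum, warm-starting every fit from the
#' previous solution, and assembles the recovered concentrations into a
#' [ConcentrationSeries-class]. Non-converged points are flagged in the
#' series, never dropped.
#'
#' @param spectra list of [Spectrum-class] with increasing timestamps (a
#'   missing timestamp on every spectrum falls back to the list order, in
#'   seconds of index).
#' @param refs a [ReferenceSet-class].
#' @param config an [UnmixConfig-class].
#' @return A [ConcentrationSeries-class].
#' @export
unmixSeries <- function(spectra, refs, config = unmixConfig()) {
  if (!is.list(spectra) || length(spectra) == 0L)
    .stopInvalid("spectra must be a non-empty list of Spectrum objects")
  times <- vapply(spectra, function(s) s@time, numeric(1))
  if (all(is.na(times))) times <- seq_along(spectra) - 1
  if (any(is.na(times)) || any(diff(times) <= 0))
    .stopInvalid("spectra must carry strictly increasing timestamps")
  n <- length(spectra)
  conc <- matrix(NA_real_, n, 3, dimnames = list(NULL,
                                                 c("c_S", "c_ES", "c_P")))
  rms <- numeric(n)
  conv <- logical(n)
  start <- NULL
  for (i in seq_len(n)) {
    r <- unmixSpectrum(spectra[[i]], refs, config, start = start)
    conc[i, ] <- r@concentrations
    rms[i] <- r@residualRMS
    conv[i] <- r@converged
    start <- r@metadata$par
  }
  new("ConcentrationSeries", time = times, conc = conc, residualRMS = rms,
      converged = conv,
      metadata = list(config = config, nNonConverged = sum(!conv)))
}

#' Check conservation of total Pchlide over a series
#'
#' The sum \eqn{c_S + c_{ES} + c_P} must stay equal to the total Pchlide in
#' solution throughout an experiment; systematic deviation indicates
#' miscalibrated references or a failed decomposition. Report-only: never
#' raises.
#'
#' @param series a [ConcentrationSeries-class] (non-empty).
#' @param expectedTotal numeric(1), known total Pchlide (uM).
#' @param relTol numeric(1), maximum tolerated relative deviation
#'   (default 0.01).
#' @return list with \code{pass}, \code{maxRelDeviation},
#'   \code{meanTotal}, \code{relDeviation} (per point) and \code{relTol}.
#' @export
conservationCheck <- function(series, expectedTotal, relTol = 0.01) {
  if (!is(series, "ConcentrationSeries") || length(series@time) == 0L)
    .stopInvalid("series must be a non-empty ConcentrationSeries")
  tot <- totalConcentration(series)
  dev <- abs(tot - expectedTotal) / expectedTotal
  list(pass = max(dev) <= relTol,
       maxRelDeviation = max(dev),
       meanTotal = mean(tot),
       relDeviation = dev,
       relTol = relTol)
}
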