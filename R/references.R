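#' @include AllClasses.R AllGenerics.R constants.R spectrum-methods.R
NULL

#' Spline-smooth a raw reference spectrum
#'
#' Reference recordings (not the mixture data) are smoothed before use in
#' unmixing, so that per-wavelength instrument noise in the references does
#' not propagate into every decomposition. A cubic smoothing spline is used;
#' by default its smoothing parameter is chosen by generalized
#' cross-validation, which needs no hand tuning and is reproducible.
#'
#' @param raw a [Spectrum-class] with at least 20 points.
#' @param smoothing \code{NULL} (default) for GCV-selected smoothing, \code{0}
#'   to return the input unchanged, or a positive number passed as the
#'   \code{spar} argument of [stats::smooth.spline()].
#' @return A [Spectrum-class] on the same grid.
#' @export
#' @examples
#' set.seed(1)
#' grid <- 600:700
#' band <- 0.2 * exp(-(grid - 651)^2 / (2 * 12^2))
#' noisy <- spectrum(grid, band + rnorm(101, sd = 0.002))
#' sm <- smoothReference(noisy)
#' max(abs(absorbance(sm) - band))  # well below the noise level
smoothReference <- function(raw, smoothing = NULL) {
  if (!is(raw, "Spectrum")) .stopInvalid("raw must be a Spectrum")
  if (length(raw@wavelength) < 20)
    .stopInvalid("need at least 20 points to smooth a reference (got ",
                 length(raw@wavelength), ")")
  if (!is.null(smoothing)) {
    if (smoothing < 0) .stopInvalid("smoothing must be >= 0")
    if (smoothing == 0) return(raw)
  }
  fit <- if (is.null(smoothing))
    stats::smooth.spline(raw@wavelength, raw@absorbance, cv = FALSE)
  else
    stats::smooth.spline(raw@wavelength, raw@absorbance, spar = smoothing)
  spectrum(raw@wavelength, stats::predict(fit, raw@wavelength)$y,
           time = raw@time, pathLength = raw@pathLength)
}

#' Convert a reference absorbance spectrum to molar absorptivity
#'
#' Beer-Lambert: \eqn{\epsilon(\lambda) = A(\lambda) / (c \, l)} with the
#' concentration expressed in mM, giving \eqn{\epsilon} in mM^-1 cm^-1.
#'
#' @param refRaw a [Spectrum-class] (typically smoothed).
#' @param concentration numeric(1), concentration at recording in uM (> 0).
#' @param pathLength numeric(1), path length in cm (defaults to the
#'   spectrum's own).
#' @return numeric, molar absorptivity curve (mM^-1 cm^-1) on the input grid.
#' @export
#' @examples
#' sp <- spectrum(c(650, 651, 652), c(0.18, 0.1872, 0.18))
#' toEpsilon(sp, concentration = 8)[2]  # 23.4 mM^-1 cm^-1
toEpsilon <- function(refRaw, concentration, pathLength = NULL) {
  if (!is(refRaw, "Spectrum")) .stopInvalid("refRaw must be a Spectrum")
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      concentration <= 0)
    .stopInvalid("concentration must be a single positive number (uM)")
  l <- if (is.null(pathLength)) refRaw@pathLength else pathLength
  refRaw@absorbance / (concentration * 1e-3 * l)
}

#' Build a calibrated ReferenceSpectrum
#'
#' Smooths a raw single-species recording, converts it to molar absorptivity,
#' and records the peak position and absorptivity within the analysis window.
#'
#' @param species character(1), \code{"S"}, \code{"ES"} or \code{"P"}.
#' @param raw a [Spectrum-class].
#' @param concentration numeric(1), uM.
#' @param smoothing see [smoothReference()].
#' @param window numeric(2), analysis window (nm) for the peak search.
#' @return A [ReferenceSpectrum-class].
#' @export
referenceSpectrum <- function(species, raw, concentration, smoothing = NULL,
                              window = c(600, 700)) {
  sm <- smoothReference(raw, smoothing)
  eps <- toEpsilon(sm, concentration)
  inWin <- sm@wavelength >= window[1] & sm@wavelength <= window[2]
  if (!any(inWin)) .stopInvalid("no points inside the analysis window")
  iPk <- which(inWin)[which.max(eps[inWin])]
  new("ReferenceSpectrum", species = species, raw = raw,
      concentration = concentration, epsilon = eps,
      peakWavelength = sm@wavelength[iPk], peakEpsilon = eps[iPk])
}

#' Assemble a ReferenceSet from three single-species recordings
#'
#' @param refS,refES,refP [ReferenceSpectrum-class] objects for substrate,
#'   complex and product.
#' @param grid numeric, common wavelength grid (nm); defaults to the portion
#'   of the S reference grid shared by all three.
#' @param window numeric(2), analysis window (nm).
#' @return A [ReferenceSet-class] with all three absorptivity curves
#'   resampled onto the common grid.
#' @export
referenceSetFromSpectra <- function(refS, refES, refP, grid = NULL,
                                    window = c(600, 700)) {
  refs <- list(S = refS, ES = refES, P = refP)
  for (nm in names(refs))
    if (!is(refs[[nm]], "ReferenceSpectrum") || refs[[nm]]@species != nm)
      .stopInvalid("ref", nm, " must be a ReferenceSpectrum for species ", nm)
  if (is.null(grid)) {
    lo <- max(vapply(refs, function(r) min(r@raw@wavelength), numeric(1)))
    hi <- min(vapply(refs, function(r) max(r@raw@wavelength), numeric(1)))
    g <- refS@raw@wavelength
    grid <- g[g >= lo & g <= hi]
  }
  eps <- vapply(refs, function(r)
    stats::approx(r@raw@wavelength, r@epsilon, xout = grid, rule = 1)$y,
    numeric(length(grid)))
  colnames(eps) <- c("S", "ES", "P")
  new("ReferenceSet", grid = as.numeric(grid), epsilon = eps,
      refConcentration = vapply(refs, function(r) r@concentration,
                                numeric(1)),
      window = window, refs = refs)
}

# Return a copy of a ReferenceSet with the ES absorptivity scaled by alpha.
.scaleEsEpsilon <- function(refs, alpha) {
  eps <- refs@epsilon
  eps[, "ES"] <- eps[, "ES"] * alpha
  initialize(refs, epsilon = eps)
}

#' Conservation-based calibration of the ES extinction coefficient
#'
#' The ES complex cannot be prepared in isolation at an exactly known
#' concentration, so its extinction coefficient is adjusted by requiring that
#' total Pchlide (free + bound) stays constant over a donor-free binding
#' series in which only S and ES are present. A single multiplicative factor
#' \eqn{\alpha} on the ES absorptivity curve is chosen to minimize the
#' relative standard deviation of \eqn{c_S(t) + c_{ES}(t)} after unmixing;
#' the scale-free objective makes the result independent of the absolute
#' concentration.
#'
#' @param series list of [Spectrum-class], a donor-free time series with at
#'   least 10 spectra.
#' @param refs a [ReferenceSet-class].
#' @param totalPchlide numeric(1), known total Pchlide in the series (uM).
#' @param config an [UnmixConfig-class] used for the inner unmixing fits.
#' @param relTol numeric(1), required relative agreement between the
#'   post-calibration mean total and \code{totalPchlide}.
#' @param bounds numeric(2), admissible range for \eqn{\alpha}; a boundary
#'   solution signals inconsistent references and raises a calibration error.
#' @return list with \code{alpha} (the factor), \code{refs} (the rescaled
#'   [ReferenceSet-class]), \code{relSD} (achieved relative SD of the total)
#'   and \code{meanTotal} (uM).
#' @export
calibrateEsEpsilon <- function(series, refs, totalPchlide,
                               config = unmixConfig(), relTol = 0.05,
                               bounds = c(0.2, 5)) {
  if (!is.list(series) || length(series) < 10)
    .stopInvalid("need a series of at least 10 spectra (got ",
                 length(series), ")")
  objective <- function(alpha) {
    sc <- .scaleEsEpsilon(refs, alpha)
    cs <- unmixSeries(series, sc, config)
    tot <- totalConcentration(cs)
    stats::sd(tot) / mean(tot)
  }
  opt <- stats::optimize(objective, interval = bounds, tol = 1e-5)
  alpha <- opt$minimum
  if (alpha <= bounds[1] * 1.01 || alpha >= bounds[2] * 0.99)
    .stopCalibration("ES calibration hit the admissible bounds (alpha = ",
                     signif(alpha, 4), "); references look inconsistent")
  scaled <- .scaleEsEpsilon(refs, alpha)
  cs <- unmixSeries(series, scaled, config)
  meanTotal <- mean(totalConcentration(cs))
  if (abs(meanTotal - totalPchlide) / totalPchlide > relTol)
    .stopCalibration("post-calibration total (", signif(meanTotal, 4),
                     " uM) disagrees with the known total Pchlide (",
                     totalPchlide, " uM)")
  list(alpha = alpha, refs = scaled, relSD = opt$objective,
       meanTotal = meanTotal)
}

#' Write / read a calibrated ReferenceSet as CSV
#'
#' The CSV holds columns \code{wavelength_nm,eps_S,eps_ES,eps_P}
#' (mM^-1 cm^-1) preceded by a \code{#}-prefixed metadata block (reference
#' concentrations and analysis window).
#'
#' @param refs a [ReferenceSet-class].
#' @param path file path.
#' @return \code{writeReferenceSet} returns \code{path} invisibly;
#'   \code{readReferenceSet} returns a [ReferenceSet-class].
#' @export
writeReferenceSet <- function(refs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  rc <- refs@refConcentration
  writeLines(c(
    sprintf("# ref_concentration_uM: S=%g ES=%g P=%g",
            rc["S"], rc["ES"], rc["P"]),
    sprintf("# analysis_window_nm: %g:%g", refs@window[1], refs@window[2])),
    con)
  utils::write.csv(data.frame(wavelength_nm = refs@grid,
                              eps_S = refs@epsilon[, "S"],
                              eps_ES = refs@epsilon[, "ES"],
                              eps_P = refs@epsilon[, "P"]),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReferenceSet
#' @export
readReferenceSet <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  rc <- .DPOR_REF_CONC
  win <- c(600, 700)
  m <- grep("ref_concentration_uM", meta, value = TRUE)
  if (length(m)) {
    vals <- regmatches(m, gregexpr("[SEP]+=[0-9.]+", m))[[1]]
    for (v in vals) {
      kv <- strsplit(v, "=")[[1]]
      rc[kv[1]] <- as.numeric(kv[2])
    }
  }
  m <- grep("analysis_window_nm", meta, value = TRUE)
  if (length(m)) {
    v <- sub("^#[^:]*: *", "", m)
    win <- as.numeric(strsplit(v, ":")[[1]])
  }
  df <- utils::read.csv(textConnection(grep("^#", lines, value = TRUE,
                                            invert = TRUE)))
  eps <- as.matrix(df[, c("eps_S", "eps_ES", "eps_P")])
  colnames(eps) <- c("S", "ES", "P")
  new("ReferenceSet", grid = df$wavelength_nm, epsilon = eps,
      refConcentration = rc, window = win)
}

#' Read a raw single-species reference spectrum with its sidecar config
#'
#' The spectrum CSV has columns \code{wavelength_nm,absorbance}; the sidecar
#' (YAML or JSON, same basename with extension \code{.yaml}/\code{.yml}/
#' \code{.json}, or given explicitly) holds \code{species},
#' \code{concentration_uM} and optionally \code{path_length_cm}.
#'
#' @param path CSV path.
#' @param sidecar optional explicit sidecar path.
#' @param smoothing,window see [referenceSpectrum()].
#' @return A [ReferenceSpectrum-class].
#' @export
readReferenceSpectrum <- function(path, sidecar = NULL, smoothing = NULL,
                                  window = c(600, 700)) {
  df <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "absorbance") %in% names(df)))
    .stopInvalid("reference CSV needs columns wavelength_nm, absorbance")
  if (is.null(sidecar)) {
    base <- sub("\\.[^.]+$", "", path)
    cand <- paste0(base, c(".yaml", ".yml", ".json"))
    sidecar <- cand[file.exists(cand)][1]
    if (is.na(sidecar)) .stopInvalid("no sidecar config found for ", path)
  }
  meta <- if (grepl("\\.json$", sidecar)) jsonlite::read_json(sidecar)
          else yaml::read_yaml(sidecar)
  raw <- spectrum(df$wavelength_nm, df$absorbance,
                  pathLength = if (is.null(meta$path_length_cm)) 1
                               else meta$path_length_cm)
  referenceSpectrum(meta$species, raw, meta$concentration_uM,
                    smoothing = smoothing, window = window)
}
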