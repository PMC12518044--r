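#' @include AllClasses.R AllGenerics.R constants.R
NULL

#' Construct a Spectrum
#'
#' @param wavelength numeric, strictly increasing wavelength grid (nm).
#' @param absorbance numeric, absorbance (AU), same length.
#' @param time numeric(1), seconds since experiment start (optional).
#' @param pathLength numeric(1), path length in cm (default 1).
#' @return A [Spectrum-class].
#' @export
#' @examples
#' sp <- spectrum(600:700, rep(0.1, 101))
#' wavelength(sp)[1:3]
spectrum <- function(wavelength, absorbance, time = NA_real_, pathLength = 1) {
  new("Spectrum", wavelength = as.numeric(wavelength),
      absorbance = as.numeric(absorbance), time = as.numeric(time)[1],
      pathLength = pathLength)
}

#' @rdname accessors
setMethod("wavelength", "Spectrum", function(x, ...) x@wavelength)

#' @rdname accessors
setMethod("absorbance", "Spectrum", function(x, ...) x@absorbance)

#' @rdname accessors
setMethod("obsTime", "Spectrum", function(x, ...) x@time)

#' @rdname accessors
setMethod("pathLength", "Spectrum", function(x, ...) x@pathLength)

setMethod("show", "Spectrum", function(object) {
  rng <- range(object@wavelength)
  cat("Spectrum: ", length(object@wavelength), " points, ",
      rng[1], "-", rng[2], " nm",
      if (!is.na(object@time)) paste0(", t = ", object@time, " s") else "",
      ", path ", object@pathLength, " cm\n", sep = "")
})

#' @describeIn resampleSpectrum Linear interpolation onto the target grid;
#'   values at grid points shared with the input are returned unchanged.
#'   Requesting points outside the input extent is an error (no
#'   extrapolation).
setMethod("resampleSpectrum", "Spectrum", function(spec, grid, ...) {
  grid <- as.numeric(grid)
  if (min(grid) < min(spec@wavelength) - 1e-9 ||
      max(grid) > max(spec@wavelength) + 1e-9)
    .stopInvalid("resampling grid extends beyond the spectrum extent (",
                 min(spec@wavelength), "-", max(spec@wavelength), " nm)")
  a <- stats::approx(spec@wavelength, spec@absorbance, xout = grid,
                     rule = 1)$y
  spectrum(grid, a, time = spec@time, pathLength = spec@pathLength)
})

# Restrict a spectrum to a wavelength window (inclusive).
.windowSpectrum <- function(spec, window) {
  keep <- spec@wavelength >= window[1] - 1e-9 &
          spec@wavelength <= window[2] + 1e-9
  spectrum(spec@wavelength[keep], spec@absorbance[keep],
           time = spec@time, pathLength = spec@pathLength)
}

#' @rdname accessors
setMethod("epsilon", "ReferenceSet", function(x, ...) x@epsilon)

#' @rdname accessors
setMethod("wavelength", "ReferenceSet", function(x, ...) x@grid)

#' @rdname accessors
setMethod("analysisWindow", "ReferenceSet", function(x, ...) x@window)

#' @rdname accessors
setMethod("refConcentration", "ReferenceSet", function(x, ...)
  x@refConcentration)

setMethod("show", "ReferenceSet", function(object) {
  pk <- apply(object@epsilon, 2, function(e) object@grid[which.max(e)])
  cat("ReferenceSet on ", length(object@grid), "-point grid (",
      min(object@grid), "-", max(object@grid), " nm), window ",
      object@window[1], "-", object@window[2], " nm\n", sep = "")
  cat("  peaks: S ", pk["S"], " nm, ES ", pk["ES"], " nm, P ", pk["P"],
      " nm\n", sep = "")
})

#' @rdname accessors
setMethod("obsTime", "ConcentrationSeries", function(x, ...) x@time)

#' @rdname accessors
#' @param species character(1), one of \code{"S"}, \code{"ES"}, \code{"P"}.
setMethod("speciesConcentration", "ConcentrationSeries",
  function(x, species, ...) {
    col <- paste0("c_", match.arg(species, c("S", "ES", "P")))
    as.numeric(x@conc[, col])
  })

#' @rdname accessors
setMethod("totalConcentration", "ConcentrationSeries", function(x, ...)
  as.numeric(rowSums(x@conc)))

#' @rdname accessors
setMethod("residualRMS", "ConcentrationSeries", function(x, ...)
  x@residualRMS)

#' @rdname accessors
setMethod("isConverged", "ConcentrationSeries", function(x, ...) x@converged)

setMethod("show", "ConcentrationSeries", function(object) {
  n <- length(object@time)
  cat("ConcentrationSeries: ", n, " points, t = ",
      if (n) paste0(min(object@time), "-", max(object@time), " s") else "-",
      "; ", sum(!object@converged), " non-converged\n", sep = "")
  if (n) {
    fin <- object@conc[n, ]
    cat(sprintf("  final: S %.3f, ES %.3f, P %.3f uM (total %.3f)\n",
                fin["c_S"], fin["c_ES"], fin["c_P"], sum(fin)))
  }
})

#' @rdname accessors
setMethod("kineticModel", "KineticFit", function(x, ...) x@model)

#' @rdname accessors
setMethod("fitFlags", "KineticFit", function(x, ...) x@flags)

#' @rdname accessors
setMethod("aicc", "KineticFit", function(x, ...) x@aicc)

#' @describeIn accessors Fitted coefficients of a kinetic model.
#' @param object a [KineticFit-class].
#' @export
setMethod("coef", "KineticFit", function(object, ...) object@params)

#' @rdname accessors
#' @export
setGeneric("fitStdErr", function(x, ...) standardGeneric("fitStdErr"))

#' @rdname accessors
setMethod("fitStdErr", "KineticFit", function(x, ...) x@stderr)

setMethod("show", "KineticFit", function(object) {
  cat("KineticFit [", object@model, "], n = ", object@nPoints,
      ", R^2 = ", signif(object@rSquared, 4),
      ", AICc = ", signif(object@aicc, 5), "\n", sep = "")
  p <- object@params
  se <- object@stderr[names(p)]
  for (nm in names(p))
    cat(sprintf("  %-10s %.6g (se %.3g)\n", nm, p[[nm]],
                if (is.na(se[[nm]])) NA else se[[nm]]))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @rdname accessors
setMethod("obsTime", "Trajectory", function(x, ...) x@time)

#' @rdname accessors
setMethod("speciesConcentration", "Trajectory", function(x, species, ...) {
  col <- paste0("c_", match.arg(species, c("S", "ES", "P", "Efree")))
  as.numeric(x@conc[, col])
})

#' @rdname accessors
setMethod("totalConcentration", "Trajectory", function(x, ...)
  as.numeric(rowSums(x@conc[, c("c_S", "c_ES", "c_P"), drop = FALSE])))

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory: ", length(object@time), " points, t = ",
      min(object@time), "-", max(object@time), " s\n", sep = "")
})

setMethod("show", "Scenario", function(object) {
  cat("Scenario '", object@name, "': ", length(object@stages), " stage(s), ",
      "grid ", object@grid[1], "-", object@grid[2], " nm step ",
      object@grid[3], ", dead time ", object@deadTime, " s\n", sep = "")
})

setMethod("show", "UnmixResult", function(object) {
  cat(sprintf(
    "UnmixResult: S %.4f, ES %.4f, P %.4f uM; baseline %.4g AU; rms %.2e AU%s\n",
    object@concentrations["S"], object@concentrations["ES"],
    object@concentrations["P"], object@baseline, object@residualRMS,
    if (object@converged) "" else " [NOT CONVERGED]"))
})
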