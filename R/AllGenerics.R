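#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Standard accessors for the package's S4 containers. Slot access from user
#' code should always go through these.
#'
#' @param x an object of the documented classes.
#' @param ... passed to methods.
#' @return The slot contents (see the method for the specific class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelength", function(x, ...) standardGeneric("wavelength"))

#' @rdname accessors
#' @export
setGeneric("absorbance", function(x, ...) standardGeneric("absorbance"))

#' @rdname accessors
#' @export
setGeneric("obsTime", function(x, ...) standardGeneric("obsTime"))

#' @rdname accessors
#' @export
setGeneric("pathLength", function(x, ...) standardGeneric("pathLength"))

#' @rdname accessors
#' @export
setGeneric("epsilon", function(x, ...) standardGeneric("epsilon"))

#' @rdname accessors
#' @export
setGeneric("analysisWindow", function(x, ...) standardGeneric("analysisWindow"))

#' @rdname accessors
#' @export
setGeneric("refConcentration", function(x, ...)
  standardGeneric("refConcentration"))

#' @rdname accessors
#' @export
setGeneric("speciesConcentration", function(x, species, ...)
  standardGeneric("speciesConcentration"))

#' @rdname accessors
#' @export
setGeneric("totalConcentration", function(x, ...)
  standardGeneric("totalConcentration"))

#' @rdname accessors
#' @export
setGeneric("residualRMS", function(x, ...) standardGeneric("residualRMS"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x, ...) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("kineticModel", function(x, ...) standardGeneric("kineticModel"))

#' @rdname accessors
#' @export
setGeneric("fitFlags", function(x, ...) standardGeneric("fitFlags"))

#' @rdname accessors
#' @export
setGeneric("aicc", function(x, ...) standardGeneric("aicc"))

#' Resample a spectrum onto a new wavelength grid
#'
#' @param spec a [Spectrum-class].
#' @param grid numeric, target wavelength grid (nm); must lie within the
#'   spectrum's extent (no extrapolation).
#' @param ... passed to methods.
#' @return A [Spectrum-class] on the new grid.
#' @export
setGeneric("resampleSpectrum", function(spec, grid, ...)
  standardGeneric("resampleSpectrum"))

#' Truncate a concentration series to the instrument dead time
#'
#' Drops all points earlier than the dead time and records the truncation in
#' the series metadata. With a zero dead time the input is returned unchanged.
#'
#' @param series a [ConcentrationSeries-class].
#' @param dead numeric(1), dead time in seconds (default 10, the time the
#'   instrument needs after an addition before reliable spectra are produced).
#' @param ... passed to methods.
#' @return The truncated [ConcentrationSeries-class].
#' @export
setGeneric("applyDeadTime", function(series, dead = 10, ...)
  standardGeneric("applyDeadTime"))
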