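#' @import methods
NULL

#' Single absorbance spectrum
#'
#' One absorbance-vs-wavelength record, optionally timestamped relative to the
#' start of an experiment. Wavelengths are in nm, absorbance in AU, path length
#' in cm (1 cm cuvettes throughout this package's defaults).
#'
#' @slot wavelength numeric, strictly increasing wavelength grid (nm).
#' @slot absorbance numeric, absorbance values (AU), same length as the grid.
#' @slot time numeric(1), seconds since experiment start (\code{NA} if untimed).
#' @slot pathLength numeric(1), optical path length in cm.
#'
#' @seealso [spectrum()], [resampleSpectrum()], [smoothReference()]
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    wavelength = "numeric",
    absorbance = "numeric",
    time       = "numeric",
    pathLength = "numeric"
  ),
  prototype(time = NA_real_, pathLength = 1)
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@wavelength) != length(object@absorbance))
    msg <- c(msg, "wavelength and absorbance must have equal length")
  if (length(object@wavelength) > 1L && any(diff(object@wavelength) <= 0))
    msg <- c(msg, "wavelength grid must be strictly increasing")
  if (any(!is.finite(object@absorbance)))
    msg <- c(msg, "absorbance must be finite")
  if (length(object@pathLength) != 1L || !is.finite(object@pathLength) ||
      object@pathLength <= 0)
    msg <- c(msg, "pathLength must be a single positive number")
  if (length(object@time) != 1L)
    msg <- c(msg, "time must be a single number (or NA)")
  if (length(msg)) msg else TRUE
})

#' Calibrated single-species reference spectrum
#'
#' A raw reference recording for one species (free Pchlide \code{S}, the
#' enzyme-substrate complex \code{ES}, or Chlide \code{P}) at a known
#' concentration, together with its smoothed molar-absorptivity curve.
#'
#' @slot species character(1), one of \code{"S"}, \code{"ES"}, \code{"P"}.
#' @slot raw [Spectrum-class], the recording the curve was derived from.
#' @slot concentration numeric(1), concentration at recording (uM).
#' @slot epsilon numeric, molar absorptivity (mM^-1 cm^-1) on the raw grid.
#' @slot peakWavelength numeric(1), wavelength of the absorptivity maximum (nm)
#'   within the analysis window.
#' @slot peakEpsilon numeric(1), absorptivity at the peak (mM^-1 cm^-1).
#'
#' @exportClass ReferenceSpectrum
setClass("ReferenceSpectrum",
  representation(
    species        = "character",
    raw            = "Spectrum",
    concentration  = "numeric",
    epsilon        = "numeric",
    peakWavelength = "numeric",
    peakEpsilon    = "numeric"
  )
)

setValidity("ReferenceSpectrum", function(object) {
  msg <- character()
  if (!object@species %in% c("S", "ES", "P"))
    msg <- c(msg, "species must be one of 'S', 'ES', 'P'")
  if (length(object@concentration) != 1L || object@concentration <= 0)
    msg <- c(msg, "concentration must be a single positive number (uM)")
  if (length(object@epsilon) != length(object@raw@wavelength))
    msg <- c(msg, "epsilon must be defined on the raw wavelength grid")
  if (any(!is.finite(object@epsilon)))
    msg <- c(msg, "epsilon must be finite")
  if (length(msg)) msg else TRUE
})

#' Set of calibrated reference spectra for unmixing
#'
#' Exactly one molar-absorptivity curve per species (\code{S}, \code{ES},
#' \code{P}), resampled onto a common wavelength grid, plus the analysis
#' window over which mixture spectra are fitted (600--700 nm by default,
#' the Q-band region where the three species are spectrally distinct).
#'
#' @slot grid numeric, common wavelength grid (nm), strictly increasing.
#' @slot epsilon numeric matrix with columns \code{S}, \code{ES}, \code{P}
#'   (mM^-1 cm^-1), one row per grid point.
#' @slot refConcentration named numeric, concentrations (uM) at which each raw
#'   reference was recorded (used to express fit amplitudes as proportionality
#'   factors).
#' @slot window numeric(2), analysis window \code{c(min, max)} in nm.
#' @slot refs list of [ReferenceSpectrum-class] objects (may be empty when the
#'   set was built directly from absorptivity curves).
#'
#' @seealso [makeReferenceSet()], [referenceSetFromSpectra()],
#'   [unmixSpectrum()]
#' @exportClass ReferenceSet
setClass("ReferenceSet",
  representation(
    grid             = "numeric",
    epsilon          = "matrix",
    refConcentration = "numeric",
    window           = "numeric",
    refs             = "list"
  ),
  prototype(window = c(600, 700), refs = list())
)

setValidity("ReferenceSet", function(object) {
  msg <- character()
  if (!identical(colnames(object@epsilon), c("S", "ES", "P")))
    msg <- c(msg, "epsilon must have columns 'S', 'ES', 'P'")
  if (nrow(object@epsilon) != length(object@grid))
    msg <- c(msg, "epsilon must have one row per grid point")
  if (length(object@grid) > 1L && any(diff(object@grid) <= 0))
    msg <- c(msg, "grid must be strictly increasing")
  if (any(!is.finite(object@epsilon)))
    msg <- c(msg, "epsilon must be finite")
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    msg <- c(msg, "window must be c(min, max) with min < max")
  if (object@window[1] < min(object@grid) - 1e-9 ||
      object@window[2] > max(object@grid) + 1e-9)
    msg <- c(msg, "analysis window must lie within the grid extent")
  if (!all(c("S", "ES", "P") %in% names(object@refConcentration)))
    msg <- c(msg, "refConcentration must be named for S, ES and P")
  if (length(msg)) msg else TRUE
})

#' Unmixing configuration
#'
#' Controls the per-spectrum least-squares decomposition. With
#' \code{fixShifts = TRUE} (default; wavelength shifts pinned at zero) the
#' model is linear in the remaining parameters and the solver converges in a
#' single Gauss-Newton step.
#'
#' @slot fixShifts logical(1), pin the three per-species wavelength shifts at
#'   0 nm (default \code{TRUE}).
#' @slot scatterExponent integer(1), exponent e of the
#'   \code{p5 * lambda^e} scatter/turbidity term; supported values are 3
#'   (default) and the physically motivated -3 and -4.
#' @slot nonnegConcentrations logical(1), constrain fitted concentrations to be
#'   nonnegative (default \code{TRUE}).
#' @slot maxShift numeric(1), bound (nm) on each wavelength shift when shifts
#'   are free.
#' @slot ftol,ptol numeric(1), solver relative tolerances on cost and
#'   parameters.
#' @slot maxIter integer(1), solver iteration cap.
#'
#' @seealso [unmixConfig()], [unmixSpectrum()]
#' @exportClass UnmixConfig
setClass("UnmixConfig",
  representation(
    fixShifts            = "logical",
    scatterExponent      = "numeric",
    nonnegConcentrations = "logical",
    maxShift             = "numeric",
    ftol                 = "numeric",
    ptol                 = "numeric",
    maxIter              = "numeric"
  ),
  prototype(fixShifts = TRUE, scatterExponent = 3,
            nonnegConcentrations = TRUE, maxShift = 3,
            ftol = 1e-10, ptol = 1e-12, maxIter = 500)
)

setValidity("UnmixConfig", function(object) {
  msg <- character()
  if (!object@scatterExponent %in% c(-4, -3, 3))
    msg <- c(msg, "scatterExponent must be one of -4, -3, 3")
  if (object@maxShift < 0)
    msg <- c(msg, "maxShift must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Result of unmixing one spectrum
#'
#' @slot concentrations named numeric(3), fitted concentrations
#'   \code{c(S=, ES=, P=)} in uM.
#' @slot baseline numeric(1), fitted flat baseline offset (AU).
#' @slot scatter numeric(1), fitted scatter coefficient (AU nm^-e for the
#'   configured exponent e).
#' @slot shifts named numeric(3), per-species wavelength shifts (nm; all 0 when
#'   shifts are fixed).
#' @slot residualRMS numeric(1), root-mean-square fit residual (AU).
#' @slot converged logical(1), solver success.
#' @slot metadata list, solver diagnostics (info code, iterations, flags).
#'
#' @exportClass UnmixResult
setClass("UnmixResult",
  representation(
    concentrations = "numeric",
    baseline       = "numeric",
    scatter        = "numeric",
    shifts         = "numeric",
    residualRMS    = "numeric",
    converged      = "logical",
    metadata       = "list"
  )
)

#' Concentration time course from a spectral series
#'
#' Aligned per-timepoint concentrations of the three species, as recovered by
#' [unmixSeries()]. The total (\code{c_S + c_ES + c_P}) is always computed on
#' demand by [totalConcentration()], never stored.
#'
#' @slot time numeric, sample times (s).
#' @slot conc numeric matrix with columns \code{c_S}, \code{c_ES}, \code{c_P}
#'   (uM), one row per time point.
#' @slot residualRMS numeric, per-point fit residual RMS (AU).
#' @slot converged logical, per-point solver success.
#' @slot metadata list, provenance (truncation, config echo, ...).
#'
#' @exportClass ConcentrationSeries
setClass("ConcentrationSeries",
  representation(
    time        = "numeric",
    conc        = "matrix",
    residualRMS = "numeric",
    converged   = "logical",
    metadata    = "list"
  ),
  prototype(metadata = list())
)

setValidity("ConcentrationSeries", function(object) {
  msg <- character()
  n <- length(object@time)
  if (!identical(colnames(object@conc), c("c_S", "c_ES", "c_P")))
    msg <- c(msg, "conc must have columns c_S, c_ES, c_P")
  if (nrow(object@conc) != n)
    msg <- c(msg, "conc must have one row per time point")
  if (length(object@residualRMS) != n || length(object@converged) != n)
    msg <- c(msg, "residualRMS and converged must align with time")
  if (n > 1L && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Fitted kinetic model for one concentration trace
#'
#' Parameter estimates, standard errors (from the local curvature of the
#' least-squares surface), the small-sample corrected Akaike score used for
#' model selection, and the data the model was fitted to.
#'
#' Models: \code{"one_phase"} is the plateau single-exponential association
#' \eqn{y(t) = y_0 + (plateau - y_0)(1 - e^{-kt})}; \code{"two_phase"} is
#' \eqn{y(t) = y_0 + span_{fast}(1 - e^{-k_{fast}t}) +
#' span_{slow}(1 - e^{-k_{slow}t})} with \eqn{k_{fast} \ge k_{slow}} enforced
#' by construction; \code{"linear"} is an ordinary straight-line initial-rate
#' fit.
#'
#' @slot model character(1), \code{"one_phase"}, \code{"two_phase"} or
#'   \code{"linear"}.
#' @slot params named numeric, fitted parameters (uM, s^-1 or uM s^-1).
#' @slot stderr named numeric, approximate standard errors per parameter.
#' @slot aicc numeric(1), small-sample corrected Akaike information criterion.
#' @slot rSquared numeric(1), coefficient of determination.
#' @slot nPoints numeric(1), number of fitted points.
#' @slot flags character, diagnostic flags (e.g. \code{"span_collapse"},
#'   \code{"unidentifiable"}); empty when the fit is clean.
#' @slot data list with elements \code{t} and \code{y}, the fitted data.
#'
#' @exportClass KineticFit
setClass("KineticFit",
  representation(
    model    = "character",
    params   = "numeric",
    stderr   = "numeric",
    aicc     = "numeric",
    rSquared = "numeric",
    nPoints  = "numeric",
    flags    = "character",
    data     = "list"
  ),
  prototype(flags = character())
)

#' Kinetic mechanism parameters
#'
#' Microscopic constants of the two-step scheme E+S <-> ES -> E+P, with
#' optional extensions: multiple ES pools with independent catalytic constants
#' (phenomenological biphasic product formation), a sequential two-site
#' (Adair-type) binding model for the (alpha-beta)2 tetramer, a
#' nonspecific-site pool, and a single-turnover mode (\code{recycle = FALSE})
#' in which sites that have released product do not rebind substrate.
#'
#' @slot kOn numeric(1), association rate constant (uM^-1 s^-1).
#' @slot kOff numeric(1), dissociation rate constant (s^-1).
#' @slot pools list of \code{list(fraction=, kCat=)}; fractions sum to 1. A
#'   single pool with \code{kCat = 0} is the donor-free binding step.
#' @slot eTotal numeric(1), total concentration of Pchlide-binding sites (uM).
#' @slot sTotal numeric(1), initial free substrate (uM); injections in event
#'   sequences add to it.
#' @slot siteModel character(1), \code{"single"} or \code{"two_site"}.
#' @slot kOn1,kOff1,kOn2,kOff2 numeric(1), sequential-site macroscopic
#'   constants (two-site model only; \code{eTotal} then counts sites, i.e.
#'   2 x tetramer concentration).
#' @slot recycle logical(1), whether product release regenerates a
#'   binding-competent site.
#' @slot nonspecificSites numeric(1), extra binding-only site pool (uM) used to
#'   emulate super-stoichiometric ES plateaus; 0 disables it.
#'
#' @seealso [mechanismParams()], [simulateMechanism()]
#' @exportClass MechanismParams
setClass("MechanismParams",
  representation(
    kOn       = "numeric",
    kOff      = "numeric",
    pools     = "list",
    eTotal    = "numeric",
    sTotal    = "numeric",
    siteModel = "character",
    kOn1      = "numeric",
    kOff1     = "numeric",
    kOn2      = "numeric",
    kOff2     = "numeric",
    recycle   = "logical",
    nonspecificSites = "numeric"
  ),
  prototype(kOn = 0, kOff = 0, pools = list(list(fraction = 1, kCat = 0)),
            eTotal = 0, sTotal = 0, siteModel = "single",
            kOn1 = 0, kOff1 = 0, kOn2 = 0, kOff2 = 0, recycle = TRUE,
            nonspecificSites = 0)
)

setValidity("MechanismParams", function(object) {
  msg <- character()
  rates <- c(object@kOn, object@kOff, object@kOn1, object@kOff1,
             object@kOn2, object@kOff2)
  if (any(rates < 0)) msg <- c(msg, "rate constants must be >= 0")
  if (object@eTotal < 0 || object@sTotal < 0)
    msg <- c(msg, "eTotal and sTotal must be >= 0")
  if (!object@siteModel %in% c("single", "two_site"))
    msg <- c(msg, "siteModel must be 'single' or 'two_site'")
  fr <- vapply(object@pools, function(p) p$fraction, numeric(1))
  kc <- vapply(object@pools, function(p) p$kCat, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) msg <- c(msg, "pool fractions must sum to 1")
  if (any(fr < 0) || any(kc < 0))
    msg <- c(msg, "pool fractions and kCat must be >= 0")
  if (object@nonspecificSites < 0)
    msg <- c(msg, "nonspecificSites must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Simulated concentration trajectory
#'
#' Ground-truth output of the mechanism simulator: species concentrations on
#' the requested time grid. Mass conservation (total Pchlide and total sites)
#' holds to integrator tolerance at every output time.
#'
#' @slot time numeric, output times (s).
#' @slot conc numeric matrix with columns \code{c_S}, \code{c_ES}, \code{c_P},
#'   \code{c_Efree} (uM).
#' @slot metadata list (stage boundaries for event sequences, totals).
#'
#' @exportClass Trajectory
setClass("Trajectory",
  representation(time = "numeric", conc = "matrix", metadata = "list"),
  prototype(metadata = list())
)

setValidity("Trajectory", function(object) {
  msg <- character()
  if (!identical(colnames(object@conc),
                 c("c_S", "c_ES", "c_P", "c_Efree")))
    msg <- c(msg, "conc must have columns c_S, c_ES, c_P, c_Efree")
  if (nrow(object@conc) != length(object@time))
    msg <- c(msg, "conc must have one row per time point")
  if (length(msg)) msg else TRUE
})

#' Synthetic experiment description
#'
#' Everything needed to generate one complete in-situ experiment: the staged
#' kinetic mechanism, the sampling scheme per stage, the wavelength grid, the
#' band shapes of the three species, and the noise model. Stage sampling
#' honours the instrument dead time: spectra earlier than \code{deadTime}
#' seconds after a stage start (an addition/mixing event) are not emitted.
#'
#' @slot name character(1).
#' @slot stages list of stages, each
#'   \code{list(duration=, sampleInterval=, params=, inject=)} where
#'   \code{params} is a [MechanismParams-class] and \code{inject} a named
#'   numeric of species amounts (uM) added at the stage start.
#' @slot grid numeric(3), \code{c(min, max, step)} wavelength grid in nm.
#' @slot bands list of per-species band shapes (see [bandShape()]).
#' @slot noise list with \code{sd} (AU), \code{baselineOffset} (AU),
#'   \code{baselineDrift} (AU/s), \code{scatterCoeff} (AU nm^-e),
#'   \code{scatterExponent}.
#' @slot deadTime numeric(1), instrument dead time (s) applied after each
#'   stage start.
#' @slot window numeric(2), analysis window (nm).
#'
#' @seealso [scenario()], [canonicalScenarios()], [generateExperiment()]
#' @exportClass Scenario
setClass("Scenario",
  representation(
    name     = "character",
    stages   = "list",
    grid     = "numeric",
    bands    = "list",
    noise    = "list",
    deadTime = "numeric",
    window   = "numeric"
  ),
  prototype(grid = c(600, 700, 1), deadTime = 10, window = c(600, 700))
)

setValidity("Scenario", function(object) {
  msg <- character()
  if (length(object@stages) < 1L) msg <- c(msg, "at least one stage required")
  for (st in object@stages) {
    if (is.null(st$duration) || st$duration <= 0)
      msg <- c(msg, "each stage needs a positive duration")
    if (is.null(st$sampleInterval) || st$sampleInterval <= 0)
      msg <- c(msg, "each stage needs a positive sampleInterval")
    if (!is(st$params, "MechanismParams"))
      msg <- c(msg, "each stage needs MechanismParams")
  }
  if (length(object@grid) != 3L || object@grid[3] <= 0 ||
      object@grid[1] >= object@grid[2])
    msg <- c(msg, "grid must be c(min, max, step) with min < max, step > 0")
  if (object@deadTime < 0) msg <- c(msg, "deadTime must be >= 0")
  if (length(msg)) msg else TRUE
})
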