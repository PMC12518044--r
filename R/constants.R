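#' @include AllClasses.R
NULL

# Q-band molar absorptivities (mM^-1 cm^-1) and peak positions (nm) of free
# Pchlide (S), the Pchlide:BchNB complex (ES) and Chlide (P) in assay buffer,
# as reported for R. capsulatus DPOR; used to anchor the synthetic references.
.DPOR_BANDS <- list(
  S  = list(center = 651, peakEpsilon = 23.4),
  ES = list(center = 633, peakEpsilon = 31.1),
  P  = list(center = 670, peakEpsilon = 44.7)
)

# Concentrations (uM) at which the single-species reference spectra are taken.
.DPOR_REF_CONC <- c(S = 8, ES = 3.5, P = 5)

# Extinction coefficients (mM^-1 cm^-1) for quantification in 80% v/v acetone
# after quenching: Chlide at 666 nm and Pchlide at 626 nm.
.EPS_CHLIDE_666 <- 74.9
.EPS_PCHLIDE_626 <- 30.4

# Molar mass of the BchNB (alpha-beta)2 tetramer, g/mol.
.BCHNB_MOLAR_MASS <- 206000

#' Reported rate constants used by the bundled scenario presets
#'
#' Observed association rate constants (s^-1) for R. capsulatus DPOR under the
#' four canonical in-situ experimental conditions emulated by
#' [canonicalScenarios()]: ES-complex formation and fast/slow product
#' (Chlide) formation phases. These are the observables the synthetic
#' scenarios are parameterized to reproduce; microscopic constants are derived
#' from them (k_on = k_obs / S_total, k_off = 0).
#'
#' @return A data.frame with columns \code{scenario}, \code{quantity},
#'   \code{k} (s^-1) and \code{uncertainty} (s^-1, the reported interval).
#' @export
#' @examples
#' dporRateConstants()
dporRateConstants <- function() {
  data.frame(
    scenario = c("fig5", "fig5", "fig5",
                 "fig6a", "fig6a", "fig6a",
                 "fig6c", "fig6c",
                 "fig7", "fig7", "fig7"),
    quantity = c("k_ES", "k_P_fast", "k_P_slow",
                 "k_ES", "k_P_fast", "k_P_slow",
                 "k_P_fast", "k_P_slow",
                 "k_ES_fast", "k_ES_slow", "k_P"),
    k = c(23e-3, 4e-3, 0.6e-3,
          230e-3, 12.2e-3, 1.2e-3,
          9e-3, 1e-3,
          18e-3, 2.2e-3, 132.2e-3),
    uncertainty = c(1e-3, 1e-3, 0.2e-3,
                    20e-3, 2.6e-3, 0.1e-3,
                    0.5e-3, 0.3e-3,
                    4e-3, 0.4e-3, 24.5e-3),
    stringsAsFactors = FALSE
  )
}

.rateConstant <- function(scenarioName, quantityName) {
  tab <- dporRateConstants()
  hit <- tab$scenario == scenarioName & tab$quantity == quantityName
  if (!any(hit)) stop("unknown rate constant: ", scenarioName, "/", quantityName)
  tab$k[hit][1]
}

.stopInvalid <- function(...) {
  stop(structure(class = c("invalidInputError", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.stopCalibration <- function(...) {
  stop(structure(class = c("calibrationFailureError", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.stopFitFailure <- function(...) {
  stop(structure(class = c("fitFailureError", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Run code with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards so generators never perturb user code.
.withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
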