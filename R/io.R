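#' @include AllClasses.R AllGenerics.R constants.R unmix.R
NULL

#' Read a wide-format spectral time series
#'
#' First column \code{wavelength_nm}; each further column is one timestamped
#' spectrum, named by its time in seconds (\code{t0}, \code{t5.0}, ...).
#' A long format (\code{time_s,wavelength_nm,absorbance}) is also accepted.
#'
#' @param path CSV path.
#' @param pathLength cm.
#' @return list of [Spectrum-class], time-ordered.
#' @export
readSpectraWide <- function(path, pathLength = 1) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (all(c("time_s", "wavelength_nm", "absorbance") %in% names(df))) {
    times <- sort(unique(df$time_s))
    return(lapply(times, function(tt) {
      sub <- df[df$time_s == tt, ]
      sub <- sub[order(sub$wavelength_nm), ]
      spectrum(sub$wavelength_nm, sub$absorbance, time = tt,
               pathLength = pathLength)
    }))
  }
  if (names(df)[1] != "wavelength_nm")
    .stopInvalid("first column must be wavelength_nm")
  tcols <- names(df)[-1]
  times <- suppressWarnings(as.numeric(sub("^t", "", tcols)))
  if (any(is.na(times)))
    .stopInvalid("spectrum columns must be named t<seconds>")
  ord <- order(times)
  lapply(ord, function(i)
    spectrum(df$wavelength_nm, df[[tcols[i]]], time = times[i],
             pathLength = pathLength))
}

#' Write a spectral series in wide format
#'
#' @param spectra list of [Spectrum-class] on a shared grid.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSpectraWide <- function(spectra, path) {
  grid <- spectra[[1]]@wavelength
  df <- data.frame(wavelength_nm = grid)
  for (sp in spectra) {
    if (!isTRUE(all.equal(sp@wavelength, grid)))
      .stopInvalid("all spectra must share one wavelength grid")
    df[[sprintf("t%g", sp@time)]] <- sp@absorbance
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a concentration series CSV
#'
#' Columns \code{time_s,c_S_uM,c_ES_uM,c_P_uM,total_uM,residual_rms,
#' converged}; the total is emitted for human readers but recomputed, never
#' trusted, on reading.
#'
#' @param series a [ConcentrationSeries-class].
#' @param path CSV path.
#' @return \code{writeConcentrationSeries}: \code{path} invisibly;
#'   \code{readConcentrationSeries}: a [ConcentrationSeries-class].
#' @export
writeConcentrationSeries <- function(series, path) {
  df <- data.frame(time_s = series@time,
                   c_S_uM = series@conc[, "c_S"],
                   c_ES_uM = series@conc[, "c_ES"],
                   c_P_uM = series@conc[, "c_P"],
                   total_uM = totalConcentration(series),
                   residual_rms = series@residualRMS,
                   converged = series@converged)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConcentrationSeries
#' @export
readConcentrationSeries <- function(path) {
  df <- utils::read.csv(path)
  conc <- as.matrix(df[, c("c_S_uM", "c_ES_uM", "c_P_uM")])
  colnames(conc) <- c("c_S", "c_ES", "c_P")
  new("ConcentrationSeries", time = df$time_s, conc = conc,
      residualRMS = df$residual_rms, converged = as.logical(df$converged),
      metadata = list(source = path))
}

#' Validate a spectra file without raising
#'
#' Structural checks on a wide or long spectra CSV: parseable numbers,
#' consistent column lengths, strictly increasing wavelengths. Problems are
#' returned as a character vector of actionable messages (empty when the
#' file is well-formed), never thrown.
#'
#' @param path CSV path.
#' @return list with \code{ok} (logical) and \code{errors} (character).
#' @export
validateSpectraFile <- function(path) {
  errors <- character()
  if (!file.exists(path))
    return(list(ok = FALSE, errors = paste0("file not found: ", path)))
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e)
                   structure(list(), parseError = conditionMessage(e)))
  if (!is.null(attr(df, "parseError")))
    return(list(ok = FALSE,
                errors = paste0("parse failure: ", attr(df, "parseError"))))
  if (!"wavelength_nm" %in% names(df))
    errors <- c(errors, "missing column wavelength_nm")
  for (cn in names(df)) {
    vals <- df[[cn]]
    bad <- which(!is.na(vals) & !is.numeric(vals) &
                   is.na(suppressWarnings(as.numeric(as.character(vals)))))
    if (is.character(vals)) {
      nonNum <- which(is.na(suppressWarnings(as.numeric(vals))) &
                        !is.na(vals) & vals != "")
      if (length(nonNum))
        errors <- c(errors, sprintf(
          "non-numeric value in column '%s', row %d ('%s')",
          cn, nonNum[1], vals[nonNum[1]]))
    } else if (length(bad)) {
      errors <- c(errors, sprintf("non-numeric cell in column '%s', row %d",
                                  cn, bad[1]))
    }
    if (any(is.na(suppressWarnings(as.numeric(as.character(vals)))) &
              !is.na(vals) & as.character(vals) != "")) next
  }
  if ("wavelength_nm" %in% names(df)) {
    wl <- suppressWarnings(as.numeric(as.character(df$wavelength_nm)))
    if (any(is.na(wl)))
      errors <- c(errors, "wavelength_nm contains non-numeric entries")
    else if (any(diff(wl) <= 0))
      errors <- c(errors, sprintf(
        "wavelength_nm is not strictly increasing (first violation at row %d)",
        which(diff(wl) <= 0)[1] + 1))
  }
  list(ok = length(errors) == 0L, errors = errors)
}
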