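# Shared fixtures, all built in code.

# Noise-free Gaussian Q-band on the standard grid.
gaussBand <- function(grid = 600:700, center = 651, sigma = 12, peak = 0.1872)
  peak * exp(-(grid - center)^2 / (2 * sigma^2))

# Truth reference set on the default grid (no noise anywhere).
truthRefs <- function() makeReferenceSet()$refs

# Forward-model a mixture spectrum from concentrations (uM) with the truth
# absorptivities, optionally with baseline/scatter terms.
mixSpectrum <- function(conc, refs = truthRefs(), p4 = 0, p5 = 0,
                        exponent = 3, time = NA_real_) {
  grid <- wavelength(refs)
  a <- as.numeric(epsilon(refs) %*% (conc[c("S", "ES", "P")] * 1e-3)) +
    p4 + p5 * grid^exponent
  dporTrace::spectrum(grid, a, time = time)
}

# Forward-model a whole trajectory into noise-free spectra.
mixSeries <- function(traj, refs = truthRefs()) {
  lapply(seq_along(obsTime(traj)), function(i) {
    cc <- c(S = speciesConcentration(traj, "S")[i],
            ES = speciesConcentration(traj, "ES")[i],
            P = speciesConcentration(traj, "P")[i])
    mixSpectrum(cc, refs, time = obsTime(traj)[i])
  })
}
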