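# shared builders for synthetic fixtures (everything is generated in code)

# one modulation set for an explicit line list, default noise-free
tinyModSet <- function(lines, background = NULL,
                       scheme = ModulationScheme(), noise = FALSE,
                       seed = NULL, detectorNm = detectionGrid()) {
  lapply(modulationWavelengths(scheme), function(l)
    simulateRawSpectrum(lines, background, l, detectorNm = detectorNm,
                        noise = noise, seed = seed))
}

lineDf <- function(center, amplitude = 5000, fwhm = 12) {
  data.frame(center_cm1 = center, amplitude = amplitude, fwhm_cm1 = fwhm)
}

# analytic derivative of a Lorentzian (amplitude A, half-width g) sampled on
# a fine wavenumber grid, as a WMRSpectrum
lorentzianDerivativeSpectrum <- function(center = 1200, A = 1, g = 6,
                                         axis = seq(600, 1800, by = 0.1)) {
  y <- -2 * A * g^2 * (axis - center) / ((axis - center)^2 + g^2)^2
  WMRSpectrum(axis, y)
}

quantifyScenario <- function(name, seed = NULL, noise = FALSE, ...) {
  run <- simulateExperiment(defaultScenario(name, ...), seed = seed,
                            noise = noise)
  quantifyRun(lapply(modulationSets(run), reconstructWMR))
}
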