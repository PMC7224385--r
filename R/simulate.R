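## Forward model: counts = Poisson( sum of Lorentzian lines mapped onto the
## detector axis at THIS step's excitation wavelength + a background that is
## a fixed function of detection wavelength, identical across steps ).

lorentzian <- function(x, center, amplitude, fwhm) {
  g <- fwhm / 2
  amplitude * g^2 / ((x - center)^2 + g^2)
}

## evaluate-with-seed, restoring the caller's RNG state afterwards
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Lorentzian line set of a scenario at a given time
#'
#' @param scenario a [Scenario-class].
#' @param tH time (h).
#' @param fwhm full width at half maximum of every line (cm^-1); default 12,
#'   typical of bacterial Raman bands.
#' @return data.frame with columns `center_cm1`, `amplitude`, `fwhm_cm1`.
#' @export
lineShapesAt <- function(scenario, tH, fwhm = 12) {
  pos <- scenario@peaks$position_cm1
  data.frame(
    center_cm1 = pos,
    amplitude = vapply(pos, function(p) peakAmplitudeAt(scenario, p, tH,
                                                        .validate = FALSE),
                       numeric(1)),
    fwhm_cm1 = fwhm)
}

#' Simulate one raw Raman spectrum
#'
#' Expected counts are the sum of Lorentzian lines, defined on the Raman-shift
#' axis and mapped to the detector via the Stokes relation at this step's
#' excitation wavelength, plus a background evaluated on the
#' detection-wavelength axis. With `noise = TRUE` counts are Poisson draws
#' around the expectation (shot noise); with `noise = FALSE` counts equal the
#' expectation exactly.
#'
#' @param lines data.frame with `center_cm1`, `amplitude` (counts, >= 0) and
#'   `fwhm_cm1` (> 0); zero rows allowed.
#' @param background function of detection wavelength (nm) returning
#'   non-negative expected background counts, or `NULL` for none.
#' @param lambdaExc excitation wavelength of this step (nm).
#' @param tH acquisition time (h).
#' @param detectorNm detection-wavelength grid; default [detectionGrid()].
#' @param noise draw Poisson shot noise?
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param integrationS integration time metadata (s).
#' @return A [RawSpectrum-class].
#' @export
simulateRawSpectrum <- function(lines, background, lambdaExc, tH = 0,
                                detectorNm = detectionGrid(),
                                noise = TRUE, seed = NULL,
                                integrationS = 50) {
  if (!length(detectorNm)) stop("empty detector axis")
  if (nrow(lines)) {
    stopifnot(all(lines$amplitude >= 0), all(lines$fwhm_cm1 > 0))
  }
  nu <- wavelengthToWavenumber(detectorNm, lambdaExc)
  expected <- numeric(length(detectorNm))
  for (i in seq_len(NROW(lines)))
    expected <- expected + lorentzian(nu, lines$center_cm1[i],
                                      lines$amplitude[i], lines$fwhm_cm1[i])
  if (!is.null(background)) {
    bg <- background(detectorNm)
    if (any(bg < 0)) stop("background must be non-negative everywhere")
    expected <- expected + bg
  }
  counts <- if (noise) withSeed(seed, stats::rpois(length(expected), expected))
            else expected
  RawSpectrum(detectorNm, counts, lambdaExc, tH, integrationS)
}

## ---- RamanRun ---------------------------------------------------------

#' A simulated modulated-Raman experiment
#'
#' One modulation set (`nSteps` raw spectra at distinct excitation
#' wavelengths) per scheduled time point, plus the provenance needed to
#' reproduce it.
#'
#' @slot sets list (one element per time point) of lists of
#'   [RawSpectrum-class], ordered by increasing timestamp.
#' @slot scenarioName condition the run was generated under.
#' @slot scheme the [ModulationScheme-class] used.
#' @slot scheduleH acquisition times (h).
#' @slot seed integer seed, or `NA`.
#' @export
setClass("RamanRun",
  representation(sets = "list", scenarioName = "character",
                 scheme = "ModulationScheme", scheduleH = "numeric",
                 seed = "numeric"))

setValidity("RamanRun", function(object) {
  msg <- character()
  if (length(object@sets) != length(object@scheduleH))
    msg <- c(msg, "one modulation set per scheduled time point required")
  if (is.unsorted(object@scheduleH, strictly = TRUE))
    msg <- c(msg, "schedule must be strictly increasing")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RamanRun", function(object) {
  cat(sprintf(
    "RamanRun '%s': %d time points x %d modulation steps (seed %s)\n",
    object@scenarioName, length(object@sets), object@scheme@nSteps,
    format(object@seed)))
})

#' @rdname RamanRun-class
#' @param object a `RamanRun`.
#' @export
modulationSets <- function(object) {
  stopifnot(is(object, "RamanRun"))
  object@sets
}

#' Simulate a full modulated-Raman time series
#'
#' One modulation set (one raw spectrum per excitation step) per scheduled
#' time point, with band amplitudes following the scenario trajectories.
#' Identical `(scenario, scheme, scheduleH, seed)` give bit-identical output.
#'
#' @param scenario a [Scenario-class].
#' @param scheme a [ModulationScheme-class].
#' @param scheduleH strictly increasing acquisition times (h) within
#'   `[0, durationH]`; default hourly from 1 h to the scenario duration.
#' @param seed integer seed for the shot noise; `NULL` leaves the RNG alone.
#' @param noise draw Poisson shot noise?
#' @param detectorNm detection-wavelength grid shared by all steps.
#' @param fwhm Lorentzian line width (cm^-1).
#' @param integrationS per-spectrum integration time metadata (s).
#' @return A [RamanRun-class].
#' @examples
#' run <- simulateExperiment(defaultScenario("no_stress"), seed = 1,
#'                           scheduleH = c(1, 2))
#' run
#' @export
simulateExperiment <- function(scenario, scheme = ModulationScheme(),
                               scheduleH = NULL, seed = NULL, noise = TRUE,
                               detectorNm = detectionGrid(scheme@centerNm),
                               fwhm = 12, integrationS = 50) {
  validObject(scenario); validObject(scheme)
  if (is.null(scheduleH))
    scheduleH <- seq(1, scenario@durationH)
  if (!length(scheduleH)) stop("empty acquisition schedule")
  if (is.unsorted(scheduleH, strictly = TRUE))
    stop("schedule must be strictly increasing")
  if (any(scheduleH < 0 | scheduleH > scenario@durationH))
    stop("schedule outside [0, durationH]")
  lambdas <- modulationWavelengths(scheme)
  bg <- backgroundFunction(scenario)
  sets <- withSeed(seed, lapply(scheduleH, function(t) {
    lines <- lineShapesAt(scenario, t, fwhm = fwhm)
    lapply(lambdas, function(l)
      simulateRawSpectrum(lines, bg, l, tH = t, detectorNm = detectorNm,
                          noise = noise, integrationS = integrationS))
  }))
  new("RamanRun", sets = sets, scenarioName = scenario@name,
      scheme = scheme, scheduleH = as.numeric(scheduleH),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}
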