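#' @import methods
NULL

## ---- ModulationScheme -------------------------------------------------

#' Excitation-wavelength modulation scheme
#'
#' The excitation laser is stepped over a small wavelength range around a
#' centre line; Raman bands shift with the excitation while the fluorescence
#' background does not, which is what the differential reconstruction
#' exploits. Defaults: five evenly spaced steps spanning 1.5 nm around
#' 785 nm.
#'
#' @slot centerNm centre excitation wavelength (nm).
#' @slot totalRangeNm total modulation span, max minus min step (nm).
#' @slot nSteps number of acquisition wavelengths (>= 3).
#' @export
setClass("ModulationScheme",
  representation(centerNm = "numeric", totalRangeNm = "numeric",
                 nSteps = "integer"),
  prototype(centerNm = 785, totalRangeNm = 1.5, nSteps = 5L))

setValidity("ModulationScheme", function(object) {
  msg <- character()
  if (length(object@centerNm) != 1 || object@centerNm <= 0)
    msg <- c(msg, "centerNm must be a single positive number")
  if (length(object@totalRangeNm) != 1 || object@totalRangeNm < 0)
    msg <- c(msg, "totalRangeNm must be a single non-negative number")
  if (length(object@nSteps) != 1 || object@nSteps < 3L)
    msg <- c(msg, "nSteps must be at least 3")
  if (length(msg)) msg else TRUE
})

#' Construct a ModulationScheme
#' @param centerNm centre excitation wavelength (nm).
#' @param totalRangeNm total modulation span (nm).
#' @param nSteps number of acquisition wavelengths.
#' @return A [ModulationScheme-class] object.
#' @examples
#' modulationWavelengths(ModulationScheme())
#' @export
ModulationScheme <- function(centerNm = 785, totalRangeNm = 1.5, nSteps = 5L) {
  new("ModulationScheme", centerNm = centerNm, totalRangeNm = totalRangeNm,
      nSteps = as.integer(nSteps))
}

#' Acquisition wavelengths of a modulation scheme
#'
#' Evenly spaced wavelengths, symmetric about the centre, with
#' max - min equal to the total range. "Five steps" means five acquisition
#' wavelengths (five recorded spectra), not five transitions.
#'
#' @param scheme a [ModulationScheme-class].
#' @return Increasing numeric vector of length `nSteps` (nm).
#' @export
modulationWavelengths <- function(scheme) {
  validObject(scheme)
  half <- scheme@totalRangeNm / 2
  seq(scheme@centerNm - half, scheme@centerNm + half,
      length.out = scheme@nSteps)
}

setMethod("show", "ModulationScheme", function(object) {
  cat(sprintf("ModulationScheme: %d steps over %.3g nm around %.6g nm\n",
              object@nSteps, object@totalRangeNm, object@centerNm))
})

## ---- RawSpectrum ------------------------------------------------------

#' A raw Raman spectrum at one modulation step
#'
#' Detector counts versus detection wavelength, recorded at a single
#' excitation wavelength.
#'
#' @slot wavelengthNm strictly increasing detection-wavelength axis (nm).
#' @slot counts non-negative counts per bin.
#' @slot excitationNm excitation wavelength of this step (nm).
#' @slot timestampH acquisition time since the start of the run (h).
#' @slot integrationS integration time (s).
#' @export
setClass("RawSpectrum",
  representation(wavelengthNm = "numeric", counts = "numeric",
                 excitationNm = "numeric", timestampH = "numeric",
                 integrationS = "numeric"))

setValidity("RawSpectrum", function(object) {
  msg <- character()
  if (length(object@wavelengthNm) != length(object@counts))
    msg <- c(msg, "axis and counts lengths differ")
  if (length(object@wavelengthNm) && any(diff(object@wavelengthNm) <= 0))
    msg <- c(msg, "detection-wavelength axis must be strictly increasing")
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    msg <- c(msg, "counts must be finite and non-negative")
  if (length(object@excitationNm) != 1 || object@excitationNm <= 0)
    msg <- c(msg, "excitationNm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a RawSpectrum
#' @param wavelengthNm detection-wavelength axis (nm), strictly increasing.
#' @param counts counts per bin (non-negative).
#' @param excitationNm excitation wavelength (nm).
#' @param timestampH acquisition time (h).
#' @param integrationS integration time (s); default 50.
#' @return A [RawSpectrum-class] object.
#' @export
RawSpectrum <- function(wavelengthNm, counts, excitationNm,
                        timestampH = 0, integrationS = 50) {
  new("RawSpectrum", wavelengthNm = as.numeric(wavelengthNm),
      counts = as.numeric(counts), excitationNm = excitationNm,
      timestampH = timestampH, integrationS = integrationS)
}

setMethod("show", "RawSpectrum", function(object) {
  cat(sprintf(
    "RawSpectrum: %d bins, %.4f-%.4f nm, excitation %.4f nm, t = %.3g h\n",
    length(object@counts), min(object@wavelengthNm),
    max(object@wavelengthNm), object@excitationNm, object@timestampH))
})

## ---- WMRSpectrum ------------------------------------------------------

#' A background-free differential (WMR) spectrum
#'
#' Signed differential intensity versus Raman shift, reconstructed from one
#' modulation set. Band centres appear as positive-to-negative zero
#' crossings; the additive fluorescence background cancels exactly.
#'
#' @slot wavenumber strictly increasing Raman-shift axis (cm^-1), referenced
#'   to the central excitation wavelength and restricted to 600-1800 cm^-1.
#' @slot intensity signed differential intensity (arbitrary units).
#' @slot timestampH acquisition time (h).
#' @slot nSource number of raw spectra behind this object.
#' @export
setClass("WMRSpectrum",
  representation(wavenumber = "numeric", intensity = "numeric",
                 timestampH = "numeric", nSource = "integer"))

setValidity("WMRSpectrum", function(object) {
  msg <- character()
  if (length(object@wavenumber) != length(object@intensity))
    msg <- c(msg, "axis and intensity lengths differ")
  if (length(object@wavenumber) && any(diff(object@wavenumber) <= 0))
    msg <- c(msg, "wavenumber axis must be strictly increasing")
  if (any(!is.finite(object@intensity)))
    msg <- c(msg, "intensity must be finite everywhere")
  if (length(msg)) msg else TRUE
})

#' Construct a WMRSpectrum
#' @param wavenumber Raman-shift axis (cm^-1), strictly increasing.
#' @param intensity signed differential intensity.
#' @param timestampH acquisition time (h).
#' @param nSource number of source raw spectra.
#' @return A [WMRSpectrum-class] object.
#' @export
WMRSpectrum <- function(wavenumber, intensity, timestampH = 0, nSource = 1L) {
  new("WMRSpectrum", wavenumber = as.numeric(wavenumber),
      intensity = as.numeric(intensity), timestampH = timestampH,
      nSource = as.integer(nSource))
}

setMethod("show", "WMRSpectrum", function(object) {
  cat(sprintf(
    "WMRSpectrum: %d bins, %.1f-%.1f cm-1, t = %.3g h, %d source spectra\n",
    length(object@intensity), min(object@wavenumber),
    max(object@wavenumber), object@timestampH, object@nSource))
})

## ---- accessors --------------------------------------------------------

#' @rdname accessors
#' @title Accessors for spectral objects
#' @description Read-only accessors for the axis, signal values and metadata
#'   of [RawSpectrum-class] and [WMRSpectrum-class] objects.
#' @param object a spectral object.
#' @export
setGeneric("spectralAxis", function(object) standardGeneric("spectralAxis"))
#' @rdname accessors
#' @export
setGeneric("intensityValues",
           function(object) standardGeneric("intensityValues"))
#' @rdname accessors
#' @export
setGeneric("timestampH", function(object) standardGeneric("timestampH"))

#' @rdname accessors
setMethod("spectralAxis", "RawSpectrum", function(object) object@wavelengthNm)
#' @rdname accessors
setMethod("spectralAxis", "WMRSpectrum", function(object) object@wavenumber)
#' @rdname accessors
setMethod("intensityValues", "RawSpectrum", function(object) object@counts)
#' @rdname accessors
setMethod("intensityValues", "WMRSpectrum", function(object) object@intensity)
#' @rdname accessors
setMethod("timestampH", "RawSpectrum", function(object) object@timestampH)
#' @rdname accessors
setMethod("timestampH", "WMRSpectrum", function(object) object@timestampH)

#' @rdname accessors
#' @export
excitationNm <- function(object) {
  stopifnot(is(object, "RawSpectrum"))
  object@excitationNm
}

#' @rdname accessors
#' @export
nSourceSpectra <- function(object) {
  stopifnot(is(object, "WMRSpectrum"))
  object@nSource
}
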