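#' Convert a Raman shift to the detection wavelength
#'
#' Applies the Stokes-shift relation \eqn{1/\lambda_{det} = 1/\lambda_{exc} -
#' \tilde\nu \times 10^{-7}} linking a Raman shift (cm\eqn{^{-1}}) to the
#' wavelength (nm) at which the scattered light is detected for a given
#' excitation wavelength.
#'
#' @param nu Raman shift in cm\eqn{^{-1}} (vectorised, must be \eqn{\ge 0}).
#' @param lambdaExc excitation wavelength in nm (> 0).
#' @return Detection wavelength(s) in nm.
#' @examples
#' wavenumberToWavelength(1000, 785)  # ~851.87 nm
#' @export
wavenumberToWavelength <- function(nu, lambdaExc) {
  if (any(lambdaExc <= 0)) stop("excitation wavelength must be positive")
  if (any(nu < 0)) stop("Raman shift must be non-negative")
  if (any(nu >= 1e7 / lambdaExc))
    stop("Raman shift at or beyond the excitation line energy is non-physical")
  1 / (1 / lambdaExc - nu * 1e-7)
}

#' Convert a detection wavelength to a Raman shift
#'
#' Inverse of [wavenumberToWavelength()].
#'
#' @param lambdaDet detection wavelength in nm.
#' @param lambdaExc excitation wavelength in nm.
#' @return Raman shift(s) in cm\eqn{^{-1}}.
#' @export
wavelengthToWavenumber <- function(lambdaDet, lambdaExc) {
  if (any(lambdaExc <= 0) || any(lambdaDet <= 0))
    stop("wavelengths must be positive")
  (1 / lambdaExc - 1 / lambdaDet) * 1e7
}

#' Detection-wavelength grid covering the fingerprint window
#'
#' Evenly spaced detector bins spanning the wavelengths that map to
#' `wnRange` at the central excitation wavelength. The default range adds
#' a 50 cm^-1 margin on both sides of the 600-1800 cm^-1 fingerprint window
#' so that every modulation step still covers it after the excitation shift.
#'
#' @param lambdaExc central excitation wavelength (nm).
#' @param nBins number of detector bins.
#' @param wnRange wavenumber window (cm^-1) the grid must cover.
#' @return Strictly increasing numeric vector of detection wavelengths (nm).
#' @export
detectionGrid <- function(lambdaExc = 785, nBins = 1024,
                          wnRange = c(550, 1850)) {
  stopifnot(nBins >= 2, length(wnRange) == 2, wnRange[1] < wnRange[2])
  seq(wavenumberToWavelength(wnRange[1], lambdaExc),
      wavenumberToWavelength(wnRange[2], lambdaExc),
      length.out = nBins)
}
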