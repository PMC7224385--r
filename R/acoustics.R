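## Acoustic trap physics in the long-wavelength (Rayleigh) regime: primary
## radiation force on a small sphere in a half-wavelength standing wave,
## levitation-balance pressure calibration against the bead's
## buoyancy-corrected weight, and the transducer voltage-to-pressure
## calibration.

#' Fluid medium properties
#'
#' @slot density mass density (kg/m^3); default water near room temperature.
#' @slot soundSpeed speed of sound (m/s).
#' @export
setClass("MediumSpec",
  representation(density = "numeric", soundSpeed = "numeric"),
  prototype(density = 998, soundSpeed = 1481))

setValidity("MediumSpec", function(object) {
  if (object@density <= 0 || object@soundSpeed <= 0)
    "density and soundSpeed must be positive" else TRUE
})

#' @rdname MediumSpec-class
#' @param density mass density (kg/m^3).
#' @param soundSpeed speed of sound (m/s).
#' @export
MediumSpec <- function(density = 998, soundSpeed = 1481)
  new("MediumSpec", density = density, soundSpeed = soundSpeed)

#' Spherical test-particle properties
#'
#' Defaults describe the 10-um polystyrene calibration bead.
#'
#' @slot radius particle radius (m).
#' @slot density mass density (kg/m^3).
#' @slot soundSpeed longitudinal sound speed in the particle (m/s).
#' @export
setClass("BeadSpec",
  representation(radius = "numeric", density = "numeric",
                 soundSpeed = "numeric"),
  prototype(radius = 5e-6, density = 1050, soundSpeed = 2350))

setValidity("BeadSpec", function(object) {
  if (object@radius <= 0 || object@density <= 0 || object@soundSpeed <= 0)
    "radius, density and soundSpeed must be positive" else TRUE
})

#' @rdname BeadSpec-class
#' @param radius particle radius (m).
#' @param density mass density (kg/m^3).
#' @param soundSpeed sound speed in the particle (m/s).
#' @export
BeadSpec <- function(radius = 5e-6, density = 1050, soundSpeed = 2350)
  new("BeadSpec", radius = radius, density = density, soundSpeed = soundSpeed)

#' Acoustic trap operating point
#'
#' @slot frequency drive frequency (Hz); default 8.07 MHz resonance.
#' @slot channelHeight resonator channel height (m); default 120 um.
#' @slot calibrationFactor pressure per drive voltage (Pa/Vpp); default
#'   18.2 kPa/Vpp.
#' @slot calibrationUncertainty fractional uncertainty of the factor;
#'   default 0.30.
#' @export
setClass("TrapConfig",
  representation(frequency = "numeric", channelHeight = "numeric",
                 calibrationFactor = "numeric",
                 calibrationUncertainty = "numeric"),
  prototype(frequency = 8.07e6, channelHeight = 120e-6,
            calibrationFactor = 18.2e3, calibrationUncertainty = 0.30))

setValidity("TrapConfig", function(object) {
  if (object@frequency <= 0 || object@calibrationFactor <= 0)
    "frequency and calibrationFactor must be positive" else TRUE
})

#' @rdname TrapConfig-class
#' @param frequency drive frequency (Hz).
#' @param channelHeight channel height (m).
#' @param calibrationFactor pressure per drive voltage (Pa/Vpp).
#' @param calibrationUncertainty fractional uncertainty.
#' @export
TrapConfig <- function(frequency = 8.07e6, channelHeight = 120e-6,
                       calibrationFactor = 18.2e3,
                       calibrationUncertainty = 0.30)
  new("TrapConfig", frequency = frequency, channelHeight = channelHeight,
      calibrationFactor = calibrationFactor,
      calibrationUncertainty = calibrationUncertainty)

## warn when outside the long-wavelength validity range
checkKa <- function(bead, medium, f) {
  ka <- 2 * pi * f / medium@soundSpeed * bead@radius
  if (ka > 0.3)
    warning(sprintf(
      "ka = %.2f exceeds 0.3: long-wavelength (Rayleigh) formulas degrade",
      ka))
  ka
}

#' Half wavelength of the standing wave
#'
#' Resonator thickness supporting a half-wavelength standing wave:
#' \eqn{c_0/(2f)}.
#'
#' @param f drive frequency (Hz).
#' @param c0 sound speed in the medium (m/s).
#' @return Length in metres.
#' @examples
#' halfWavelength(8.07e6, 1481) * 1e6  # ~91.8 um, close to the 120 um channel
#' @export
halfWavelength <- function(f, c0) {
  if (f <= 0 || c0 <= 0) stop("frequency and sound speed must be positive")
  c0 / (2 * f)
}

#' Acoustophoretic contrast factor
#'
#' \deqn{\Phi = f_1/3 + f_2/2,\quad f_1 = 1 - \tilde\kappa,\quad
#'   f_2 = 2(\tilde\rho - 1)/(2\tilde\rho + 1)}
#' with \eqn{\tilde\rho = \rho_p/\rho_0} and
#' \eqn{\tilde\kappa = \rho_0 c_0^2 / (\rho_p c_p^2)} (compressibility
#' ratio). Particles with \eqn{\Phi > 0} collect at the pressure node.
#'
#' @param bead a [BeadSpec-class].
#' @param medium a [MediumSpec-class].
#' @return Dimensionless contrast factor.
#' @examples
#' contrastFactor(BeadSpec(), MediumSpec())  # polystyrene in water, ~0.224
#' @export
contrastFactor <- function(bead = BeadSpec(), medium = MediumSpec()) {
  validObject(bead); validObject(medium)
  rhoT <- bead@density / medium@density
  kapT <- (medium@density * medium@soundSpeed^2) /
          (bead@density * bead@soundSpeed^2)
  (1 - kapT) / 3 + (rhoT - 1) / (2 * rhoT + 1)
}

#' Primary radiation force in a planar standing wave
#'
#' \deqn{F(z) = 4\pi \Phi k a^3 E_{ac} \sin(2kz)}
#' with \eqn{k = 2\pi f/c_0} and acoustic energy density
#' \eqn{E_{ac} = p_a^2/(4\rho_0 c_0^2)}. For \eqn{\Phi > 0} the force is
#' directed toward the pressure node.
#'
#' @param bead a [BeadSpec-class].
#' @param medium a [MediumSpec-class].
#' @param pA pressure amplitude (Pa, >= 0).
#' @param f drive frequency (Hz).
#' @param z position along the standing wave (m); vectorised.
#' @return Force in newtons (same sign as \eqn{\sin(2kz)} for \eqn{\Phi>0}).
#' @export
radiationForce <- function(bead, medium, pA, f, z) {
  if (pA < 0) stop("pressure amplitude must be non-negative")
  checkKa(bead, medium, f)
  k <- 2 * pi * f / medium@soundSpeed
  eAc <- pA^2 / (4 * medium@density * medium@soundSpeed^2)
  4 * pi * contrastFactor(bead, medium) * k * bead@radius^3 * eAc *
    sin(2 * k * z)
}

#' Buoyancy-corrected weight of the bead
#'
#' \eqn{(4/3)\pi a^3 (\rho_p - \rho_0) g}.
#'
#' @param bead a [BeadSpec-class].
#' @param medium a [MediumSpec-class].
#' @param g gravitational acceleration (m/s^2).
#' @return Net weight in newtons (negative for buoyant particles).
#' @export
netWeight <- function(bead = BeadSpec(), medium = MediumSpec(), g = 9.81) {
  validObject(bead); validObject(medium)
  4 / 3 * pi * bead@radius^3 * (bead@density - medium@density) * g
}

#' Minimal pressure amplitude that levitates the bead
#'
#' Smallest amplitude for which the maximal radiation force over z balances
#' the bead's net weight (the levitation-balance calibration). Closed form
#' \deqn{p_{min} = \sqrt{4\rho_0 c_0^2 \Delta\rho\, g / (3\Phi k)}}
#' or, with `method = "root"`, a numerical root of
#' \eqn{\max_z F(z; p) - W} for cross-validation.
#'
#' @param bead a [BeadSpec-class].
#' @param medium a [MediumSpec-class].
#' @param f drive frequency (Hz).
#' @param g gravitational acceleration (m/s^2).
#' @param method `"closed"` (default) or `"root"`.
#' @return Pressure amplitude in pascals.
#' @examples
#' levitationThresholdPressure() / 1e3  # ~13.9 kPa for the 10-um bead
#' @export
levitationThresholdPressure <- function(bead = BeadSpec(),
                                        medium = MediumSpec(),
                                        f = 8.07e6, g = 9.81,
                                        method = c("closed", "root")) {
  method <- match.arg(method)
  phi <- contrastFactor(bead, medium)
  if (phi <= 0)
    stop("non-positive contrast factor: no levitation against gravity")
  checkKa(bead, medium, f)
  k <- 2 * pi * f / medium@soundSpeed
  w <- abs(netWeight(bead, medium, g))
  if (method == "closed")
    return(sqrt(4 * medium@density * medium@soundSpeed^2 *
                  abs(bead@density - medium@density) * g / (3 * phi * k)))
  maxForce <- function(p)
    pi * phi * k * bead@radius^3 * p^2 / (medium@density * medium@soundSpeed^2)
  stats::uniroot(function(p) maxForce(p) - w, c(1e-6, 1e9),
                 tol = 1e-12)$root
}

#' Convert drive voltage to pressure amplitude
#'
#' Applies the measured transducer calibration factor, returning the central
#' estimate and the bounds implied by the calibration uncertainty.
#'
#' @param vpp drive voltage (Vpp, >= 0).
#' @param config a [TrapConfig-class].
#' @return list with `pA`, `lower`, `upper` (Pa).
#' @examples
#' voltageToPressure(3)$pA / 1e3   # 54.6 kPa holding amplitude
#' voltageToPressure(7)$pA / 1e3   # 127.4 kPa trapping amplitude
#' @export
voltageToPressure <- function(vpp, config = TrapConfig()) {
  if (any(vpp < 0)) stop("drive voltage must be non-negative")
  validObject(config)
  p <- config@calibrationFactor * vpp
  list(pA = p, lower = p * (1 - config@calibrationUncertainty),
       upper = p * (1 + config@calibrationUncertainty))
}

#' Convert pressure amplitude to drive voltage
#'
#' Inverse of [voltageToPressure()].
#'
#' @param pA pressure amplitude (Pa, >= 0).
#' @param config a [TrapConfig-class].
#' @return Drive voltage (Vpp).
#' @export
pressureToVoltage <- function(pA, config = TrapConfig()) {
  if (any(pA < 0)) stop("pressure amplitude must be non-negative")
  validObject(config)
  pA / config@calibrationFactor
}

#' All intermediate trap quantities at an operating point
#'
#' Convenience report of the derived quantities (wavenumber k, energy
#' density, contrast factor, maximal force, net weight, levitation
#' threshold) for a bead/medium/trap combination at a given drive voltage.
#'
#' @param vpp drive voltage (Vpp).
#' @param bead a [BeadSpec-class].
#' @param medium a [MediumSpec-class].
#' @param config a [TrapConfig-class].
#' @return Named list of quantities in SI units.
#' @export
trapOperatingPoint <- function(vpp = 3, bead = BeadSpec(),
                               medium = MediumSpec(),
                               config = TrapConfig()) {
  v2p <- voltageToPressure(vpp, config)
  k <- 2 * pi * config@frequency / medium@soundSpeed
  list(vpp = vpp, pA = v2p$pA, pLower = v2p$lower, pUpper = v2p$upper,
       k = k, ka = k * bead@radius,
       energyDensity = v2p$pA^2 / (4 * medium@density * medium@soundSpeed^2),
       contrastFactor = contrastFactor(bead, medium),
       halfWavelength = halfWavelength(config@frequency, medium@soundSpeed),
       maxForce = pi * contrastFactor(bead, medium) * k * bead@radius^3 *
         v2p$pA^2 / (medium@density * medium@soundSpeed^2),
       netWeight = netWeight(bead, medium),
       levitationThreshold = levitationThresholdPressure(bead, medium,
                                                         config@frequency))
}
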