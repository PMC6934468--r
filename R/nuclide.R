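# Physical constants used throughout (units convention: nmol, L, min, Bq, Gy)
.AVOGADRO <- 6.02214076e23   # mol^-1
.KEV_TO_J <- 1.602176634e-16 # J per keV

#' Radionuclide description
#'
#' A nuclide carries its physical half-life and the mean energy emitted per
#' decay, split into the electron component (beta spectrum plus conversion and
#' Auger electrons, absorbed locally in sphere dosimetry) and the photon
#' component (gamma and X rays).
#'
#' @param name Identifier, e.g. `"Lu-177"`.
#' @param half_life_min Physical half-life in minutes. Must be positive.
#' @param delta_electron_J Mean electron energy emitted per decay (J).
#' @param delta_photon_J Mean photon energy emitted per decay (J).
#'
#' @return An object of class `nuclide` with fields `name`, `half_life`
#'   (min), `lambda_phys` (1/min), `delta_electron` and `delta_photon` (J).
#' @examples
#' lu <- lu177()
#' lu$lambda_phys * lu$half_life  # = log(2)
#' @export
nuclide <- function(name, half_life_min, delta_electron_J, delta_photon_J) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life_min) || length(half_life_min) != 1L ||
      !is.finite(half_life_min) || half_life_min <= 0) {
    stop("half_life_min must be a single positive number")
  }
  if (delta_electron_J < 0 || delta_photon_J < 0) {
    stop("mean emission energies must be >= 0")
  }
  structure(
    list(
      name = name,
      half_life = half_life_min,
      lambda_phys = log(2) / half_life_min,
      delta_electron = delta_electron_J,
      delta_photon = delta_photon_J
    ),
    class = "nuclide"
  )
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf(
    "<nuclide %s> T1/2 = %.4g min, lambda = %.4g /min, De = %.4g keV, Dp = %.4g keV\n",
    x$name, x$half_life, x$lambda_phys,
    x$delta_electron / .KEV_TO_J, x$delta_photon / .KEV_TO_J
  ))
  invisible(x)
}

#' Lutetium-177
#'
#' Half-life 6.647 d. Mean electron energy per decay 147.9 keV (beta plus
#' conversion/Auger electrons), mean photon energy 35.0 keV, from standard
#' decay data compilations.
#' @return A [nuclide()].
#' @export
lu177 <- function() {
  nuclide("Lu-177",
          half_life_min = 6.647 * 24 * 60,
          delta_electron_J = 147.9 * .KEV_TO_J,
          delta_photon_J = 35.0 * .KEV_TO_J)
}

#' Gallium-68
#'
#' Half-life 67.71 min. Mean positron energy per decay 740 keV (836 keV mean
#' beta+ energy at 88.9% yield), photon component dominated by annihilation
#' radiation (~944 keV per decay).
#' @return A [nuclide()].
#' @export
ga68 <- function() {
  nuclide("Ga-68",
          half_life_min = 67.71,
          delta_electron_J = 740 * .KEV_TO_J,
          delta_photon_J = 944 * .KEV_TO_J)
}

#' Labelled (hot) molar amount implied by an injected activity
#'
#' Converts activity to the molar amount of radiolabelled ligand via
#' \eqn{n = A_0 / (\lambda N_A)} with \eqn{\lambda} in 1/s, returned in nmol.
#' For 7.3 GBq Lu-177 this is about 10 nmol; for 150 MBq Ga-68 about
#' 1.5e-3 nmol, negligible against typical 1-10 nmol imaging amounts.
#'
#' @param activity_bq Injected activity (Bq), non-negative.
#' @param nuclide A [nuclide()].
#' @return Amount of hot ligand in nmol.
#' @export
hot_amount_from_activity <- function(activity_bq, nuclide) {
  stopifnot(inherits(nuclide, "nuclide"))
  if (!is.numeric(activity_bq) || length(activity_bq) != 1L ||
      !is.finite(activity_bq) || activity_bq < 0) {
    stop("activity_bq must be a single non-negative number")
  }
  lambda_per_s <- nuclide$lambda_phys / 60
  activity_bq / (lambda_per_s * .AVOGADRO) * 1e9
}

#' Activity of a hot molar amount
#'
#' Inverse of [hot_amount_from_activity()]: \eqn{A = \lambda n N_A} with
#' \eqn{\lambda} in 1/s and `amount_nmol` converted to mol.
#' @param amount_nmol Hot ligand amount (nmol).
#' @param nuclide A [nuclide()].
#' @return Activity in Bq.
#' @export
activity_from_amount <- function(amount_nmol, nuclide) {
  stopifnot(inherits(nuclide, "nuclide"))
  (nuclide$lambda_phys / 60) * amount_nmol * 1e-9 * .AVOGADRO
}
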