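#' Physical constants and unit conversions
#'
#' All engines work internally in angular frequency units of rad/fs, with
#' energies supplied in wavenumbers (cm^-1) and rates in ps^-1. A quantity
#' of 1 cm^-1 corresponds to an angular frequency of
#' 2 * pi * c = 1.883652e-4 rad/fs.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{speed_of_light_cm_fs}{Speed of light, cm/fs.}
#'   \item{boltzmann_cm1_K}{Boltzmann constant, cm^-1/K.}
#'   \item{cm1_to_radfs}{Angular frequency (rad/fs) of a 1 cm^-1 quantum.}
#' }
#' @export
eet_constants <- list(
  speed_of_light_cm_fs = 2.99792458e-5,
  boltzmann_cm1_K      = 0.695034800,
  cm1_to_radfs         = 2 * pi * 2.99792458e-5
)

#' Convert a wavenumber to angular frequency
#'
#' @param x Energy or frequency in cm^-1.
#' @return Angular frequency in rad/fs.
#' @export
cm1_to_angfreq <- function(x) x * eet_constants$cm1_to_radfs

#' Convert an angular frequency to a wavenumber
#'
#' @param omega Angular frequency in rad/fs.
#' @return Energy in cm^-1.
#' @export
angfreq_to_cm1 <- function(omega) omega / eet_constants$cm1_to_radfs

#' Convert a correlation time in fs to a cutoff frequency in cm^-1
#'
#' The Drude cutoff is the inverse bath correlation time; a correlation
#' time of 50 fs corresponds to roughly 106.2 cm^-1.
#'
#' @param tau_fs Correlation time in fs.
#' @return Cutoff in cm^-1.
#' @export
corrtime_fs_to_cm1 <- function(tau_fs) {
  stopifnot(is.numeric(tau_fs), all(tau_fs > 0))
  1 / (tau_fs * eet_constants$cm1_to_radfs)
}

# rate conversions: trapping/loss rates are quoted in ps^-1, propagation in fs
rate_ps_to_fs <- function(rate_ps) rate_ps / 1000
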