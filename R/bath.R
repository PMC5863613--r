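#' Bath parameters for a Drude-Lorentz environment
#'
#' Every site couples to its own, identical overdamped bath with spectral
#' density `J(omega) = 2 * lambda * nu * omega / (omega^2 + nu^2)`, where
#' `lambda` is the reorganization energy and `nu` the cutoff (inverse bath
#' correlation time).
#'
#' @param lambda_cm1 Reorganization energy lambda in cm^-1 (>= 0).
#' @param nu_inv_fs Bath correlation time nu^-1 in fs (> 0). Stored
#'   internally as the cutoff `nu` in cm^-1.
#' @param temperature_K Temperature in K (> 0).
#' @return A `bath_parameters` object with elements `lambda_cm1`, `nu_cm1`,
#'   `temperature_K`.
#' @examples
#' bath_parameters(35, 50, 300)  # the standard light-harvesting bath
#' @export
bath_parameters <- function(lambda_cm1 = 35, nu_inv_fs = 50, temperature_K = 300) {
  if (lambda_cm1 < 0) stop("lambda_cm1 must be >= 0", call. = FALSE)
  if (nu_inv_fs <= 0) stop("nu_inv_fs must be > 0", call. = FALSE)
  if (temperature_K <= 0) stop("temperature_K must be > 0", call. = FALSE)
  structure(list(lambda_cm1 = lambda_cm1,
                 nu_cm1 = corrtime_fs_to_cm1(nu_inv_fs),
                 temperature_K = temperature_K),
            class = "bath_parameters")
}

#' Trapping and loss parameters
#'
#' Irreversible capture of the excitation at the acceptor pigment (coupling
#' to the reaction center) is modelled by a trapping rate `Gamma_trap`
#' acting on the acceptor population; radiative/non-radiative decay is a
#' uniform loss rate `Gamma_loss` on every site. Both enter the dynamics as
#' anti-Hermitian parts of the Hamiltonian with coefficient Gamma/2, so an
#' isolated population subject to rate Gamma decays as `exp(-Gamma * t)`.
#'
#' @param donor 1-based index of the initially excited pigment.
#' @param acceptor 1-based index of the trapping pigment.
#' @param gamma_trap_ps Trapping rate in ps^-1 (> 0); the default is the
#'   conventional `1/(1 ps)`.
#' @param gamma_loss_ps Loss rate in ps^-1 (>= 0); default `1/(0.25 ns)`.
#' @return A `sink_parameters` object.
#' @export
sink_parameters <- function(donor = 1, acceptor = 3,
                            gamma_trap_ps = 1, gamma_loss_ps = 1 / 250) {
  donor <- as.integer(donor); acceptor <- as.integer(acceptor)
  if (donor == acceptor) stop("donor and acceptor must differ", call. = FALSE)
  if (donor < 1 || acceptor < 1) stop("site indices are 1-based", call. = FALSE)
  if (gamma_trap_ps <= 0) stop("gamma_trap_ps must be > 0", call. = FALSE)
  if (gamma_loss_ps < 0) stop("gamma_loss_ps must be >= 0", call. = FALSE)
  structure(list(donor = donor, acceptor = acceptor,
                 gamma_trap_ps = gamma_trap_ps, gamma_loss_ps = gamma_loss_ps),
            class = "sink_parameters")
}

#' Drude-Lorentz spectral density
#'
#' `J(omega) = 2 * lambda * nu * omega / (omega^2 + nu^2)`, an odd function
#' of omega that peaks at `J(nu) = lambda`.
#'
#' @param omega_cm1 Frequency in cm^-1 (vectorized).
#' @param bath A [bath_parameters()] object.
#' @return Spectral density in cm^-1.
#' @export
drude_lorentz <- function(omega_cm1, bath) {
  stopifnot(inherits(bath, "bath_parameters"))
  2 * bath$lambda_cm1 * bath$nu_cm1 * omega_cm1 / (omega_cm1^2 + bath$nu_cm1^2)
}

#' Bose-Einstein occupation number
#'
#' `n(omega) = 1 / (exp(omega / kT) - 1)` with omega and kT in the same
#' units; satisfies `n(-omega) = -(1 + n(omega))`. The caller must handle
#' the omega -> 0 limit separately.
#'
#' @param omega_cm1 Frequency in cm^-1, nonzero (vectorized).
#' @param temperature_K Temperature in K.
#' @return Occupation number.
#' @export
bose_occupation <- function(omega_cm1, temperature_K) {
  if (any(omega_cm1 == 0)) stop("omega must be nonzero; use the omega -> 0 limit branch",
                                call. = FALSE)
  kT <- eet_constants$boltzmann_cm1_K * temperature_K
  1 / expm1(omega_cm1 / kT)
}

#' Effective non-Hermitian Hamiltonian with trapping and loss
#'
#' `H_eff = H - i (Gamma_trap / 2) |acc><acc| - i (Gamma_loss / 2) I`, in
#' cm^-1-equivalent units: rates in ps^-1 are converted so that a
#' population subject to rate Gamma decays as `exp(-Gamma * t)` under
#' `d rho/dt = -i (H_eff rho - rho H_eff^dagger)` in angular units.
#'
#' @param h A [frenkel_hamiltonian()].
#' @param sink A [sink_parameters()].
#' @return Complex matrix in cm^-1-equivalent units (convert with
#'   [cm1_to_angfreq()] before propagating in fs).
#' @export
effective_hamiltonian <- function(h, sink) {
  stopifnot(inherits(h, "frenkel_hamiltonian"), inherits(sink, "sink_parameters"))
  if (sink$acceptor > h$n_sites || sink$donor > h$n_sites)
    stop("sink indices exceed n_sites", call. = FALSE)
  m <- as.matrix(h) + 0i
  # rate [ps^-1] -> fs^-1 -> cm^-1 equivalent, halved for amplitude decay
  gt <- rate_ps_to_fs(sink$gamma_trap_ps) / eet_constants$cm1_to_radfs
  gl <- rate_ps_to_fs(sink$gamma_loss_ps) / eet_constants$cm1_to_radfs
  m[sink$acceptor, sink$acceptor] <- m[sink$acceptor, sink$acceptor] - 1i * gt / 2
  diag(m) <- diag(m) - 1i * gl / 2
  m
}
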