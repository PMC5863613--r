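#' Coherent propagation with trapping and loss (reference engine)
#'
#' Integrates `d rho/dt = -i (H_eff rho - rho H_eff^dagger)` with a
#' fixed-step 4th-order Runge-Kutta scheme, where `H_eff` carries the
#' anti-Hermitian trapping/loss terms of [effective_hamiltonian()]. This is
#' the zero-reorganization-energy limit of both the HEOM and the secular
#' Redfield engines and serves as their common reference.
#'
#' The Hamiltonian is shifted by its mean site energy before propagation;
#' the shift is a global phase with no effect on the density matrix.
#'
#' @param h A [frenkel_hamiltonian()].
#' @param sink A [sink_parameters()].
#' @param grid A [time_grid()]; default 1 fs steps, storing every 20 steps.
#' @param tail_tol Stop once the excited population falls below this.
#' @return An `eet_trajectory`.
#' @export
propagate_unitary_sink <- function(h, sink, grid = time_grid(dt_fs = 1, store_every = 20),
                                   tail_tol = 1e-4) {
  stopifnot(inherits(h, "frenkel_hamiltonian"), inherits(grid, "time_grid"))
  n <- h$n_sites
  Heff <- (effective_hamiltonian(h, sink) - diag(mean(h$energies), n)) *
    eet_constants$cm1_to_radfs
  rho0 <- matrix(0 + 0i, n, n)
  rho0[sink$donor, sink$donor] <- 1 + 0i
  n_steps <- ceiling(grid$t_max_fs / grid$dt_fs)
  res <- cpp_propagate_unitary_sink(Heff, rho0, grid$dt_fs, n_steps,
                                    grid$store_every, tail_tol)
  if (res$unstable)
    stop("unitary propagation unstable (population overshoot); reduce dt below ",
         grid$dt_fs, " fs", call. = FALSE)
  new_trajectory(res$times, res$pops, res$total, sink, "unitary")
}
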