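#' Diagonalize a Frenkel Hamiltonian into the exciton basis
#'
#' Eigenvalues are returned in ascending order; each eigenvector's sign is
#' fixed so that its largest-magnitude component is positive (first such
#' component on ties).
#'
#' @param h A [frenkel_hamiltonian()] or real symmetric matrix (cm^-1).
#' @return An `exciton_basis` object: `eigenvalues` (cm^-1, ascending) and
#'   `eigenvectors` (orthonormal columns, site x exciton).
#' @export
diagonalize <- function(h) {
  m <- if (inherits(h, "frenkel_hamiltonian")) as.matrix(h) else as.matrix(h)
  e <- eigen(m, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  for (a in seq_along(vals)) {
    i <- which.max(abs(vecs[, a]))
    if (vecs[i, a] < 0) vecs[, a] <- -vecs[, a]
  }
  structure(list(eigenvalues = vals, eigenvectors = vecs),
            class = "exciton_basis")
}

#' Secular Redfield rates in the exciton basis
#'
#' Second-order, Markovian rates for a Drude-Lorentz bath with identical
#' per-site environments. For excitons a, b with frequency gap
#' `omega = E_a - E_b`:
#' `k_{a->b} = 2 J(omega) (n(omega) + 1) * sum_m |c_m^a|^2 |c_m^b|^2`
#' (angular units); uphill rates follow from the same expression and obey
#' detailed balance exactly. Near-degenerate pairs (< 1e-6 cm^-1) and the
#' pure-dephasing channel use the analytic omega -> 0 limit
#' `2 J(omega) n(omega) -> 4 lambda k_B T / nu`. Coherence decay is half
#' the total depopulation of the pair plus pure dephasing plus the sink
#' contribution; trapping enters as per-exciton rates
#' `Gamma_a = Gamma_trap |c_acc^a|^2`.
#'
#' @param basis An [diagonalize()] result.
#' @param bath A [bath_parameters()].
#' @param sink A [sink_parameters()].
#' @return A `redfield_rates` object: `population_rates` (fs^-1 matrix,
#'   entry \[a, b\] = k_{a->b}), `dephasing_rates` (fs^-1, total coherence
#'   decay), `sink_rates` (per-exciton trap rates and uniform loss, fs^-1),
#'   and the exciton frequencies `omega_cm1`.
#' @export
secular_rates <- function(basis, bath, sink) {
  stopifnot(inherits(basis, "exciton_basis"), inherits(bath, "bath_parameters"),
            inherits(sink, "sink_parameters"))
  C <- basis$eigenvectors
  n <- ncol(C)
  if (sink$acceptor > n) stop("acceptor index exceeds system size", call. = FALSE)
  E <- basis$eigenvalues
  kT <- eet_constants$boltzmann_cm1_K * bath$temperature_K
  rate0_cm <- 4 * bath$lambda_cm1 * kT / bath$nu_cm1  # omega -> 0 limit of 2 J n
  Csq <- C^2
  overlap <- t(Csq) %*% Csq                            # sum_m |c_m^a|^2 |c_m^b|^2
  omega <- outer(E, E, "-")                            # omega_ab = E_a - E_b
  k_cm <- matrix(rate0_cm, n, n)
  nd <- abs(omega) >= 1e-6
  k_cm[nd] <- 2 * drude_lorentz(omega[nd], bath) *
    (bose_occupation(omega[nd], bath$temperature_K) + 1)
  k <- k_cm * overlap * eet_constants$cm1_to_radfs     # fs^-1
  diag(k) <- 0

  depop <- rowSums(k)
  pd <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n))
    pd[a, b] <- sum((Csq[, a] - Csq[, b])^2) / 2
  pd <- pd * rate0_cm * eet_constants$cm1_to_radfs

  g_trap <- rate_ps_to_fs(sink$gamma_trap_ps) * Csq[sink$acceptor, ]
  g_loss <- rate_ps_to_fs(sink$gamma_loss_ps)
  deph <- (outer(depop, depop, "+") / 2) + pd +
    outer(g_trap, g_trap, "+") / 2 + g_loss
  diag(deph) <- 0
  structure(list(population_rates = k, dephasing_rates = deph,
                 sink_rates = list(trap = g_trap, loss = g_loss),
                 omega_cm1 = omega),
            class = "redfield_rates")
}

# Pauli generator with sink decay, and its symmetrized eigendecomposition.
# Detailed balance makes K similar to a symmetric matrix via
# D = diag(exp(-beta E / 2)) (energies shifted for numerical range), so the
# propagator is exact: p(t) = D U exp(L t) U' D^-1 p0.
redfield_generator <- function(rates, E_cm1, temperature_K) {
  k <- rates$population_rates
  n <- nrow(k)
  K <- t(k)
  diag(K) <- -rowSums(k) - rates$sink_rates$trap - rates$sink_rates$loss
  kT <- eet_constants$boltzmann_cm1_K * temperature_K
  d <- exp(-(E_cm1 - min(E_cm1)) / (2 * kT))
  S <- (1 / d) * K * rep(d, each = n)   # D^-1/2 K D^1/2
  S <- (S + t(S)) / 2                   # symmetrize roundoff
  es <- eigen(S, symmetric = TRUE)
  list(d = d, U = es$vectors, lambda = es$values)
}

#' Propagate exciton dynamics with the secular Redfield master equation
#'
#' Exciton populations follow the Pauli master equation with per-exciton
#' trapping and uniform loss; exciton coherences, seeded by the site-local
#' donor state, evolve as `exp(-(i omega_ab + gamma_ab) t)`. Site
#' populations are recovered by back-transformation including the
#' coherence terms. The propagator is evaluated in closed form via the
#' spectral decomposition of the (detailed-balance-symmetrizable) rate
#' generator, so there is no integration error on the stored grid.
#'
#' @inheritParams propagate_heom
#' @param grid A [time_grid()]; only `t_max_fs` and the storage interval
#'   `dt_fs * store_every` matter since propagation is exact.
#' @return An `eet_trajectory`.
#' @export
propagate_secular_redfield <- function(h, bath, sink,
                                       grid = time_grid(dt_fs = 1, store_every = 20),
                                       tail_tol = 1e-4) {
  stopifnot(inherits(h, "frenkel_hamiltonian"))
  n <- h$n_sites
  basis <- diagonalize(h)
  rates <- secular_rates(basis, bath, sink)
  gen <- redfield_generator(rates, basis$eigenvalues, bath$temperature_K)
  C <- basis$eigenvectors
  p0 <- C[sink$donor, ]^2

  times <- seq(0, grid$t_max_fs, by = grid$dt_fs * grid$store_every)
  # populations: T x n excitons
  w0 <- crossprod(gen$U, p0 / gen$d)
  Et <- exp(outer(times, gen$lambda))           # T x n modes
  P <- (Et * rep(as.vector(w0), each = length(times))) %*% t(gen$U * gen$d)
  total <- rowSums(P)

  # site populations from exciton populations ...
  Csq <- C^2
  pops <- P %*% t(Csq)
  # ... plus decaying coherence terms from the site-local initial state
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  amp <- C[sink$donor, pairs[, 1]] * C[sink$donor, pairs[, 2]]
  w_ab <- cm1_to_angfreq(basis$eigenvalues[pairs[, 1]] - basis$eigenvalues[pairs[, 2]])
  g_ab <- rates$dephasing_rates[pairs]
  Epair <- 2 * exp(-outer(times, g_ab)) * cos(outer(times, w_ab)) *
    rep(amp, each = length(times))
  M <- C[, pairs[, 1], drop = FALSE] * C[, pairs[, 2], drop = FALSE]  # site x pair
  pops <- pops + Epair %*% t(M)

  below <- which(total < tail_tol)
  idx <- seq_len(if (length(below)) below[1] else length(times))
  new_trajectory(times[idx], pops[idx, , drop = FALSE], total[idx], sink, "redfield")
}

# Closed-form transfer statistics for the secular Redfield model, used as
# an independent oracle for the trajectory + trapezoid + tail pipeline.
redfield_stats_closed_form <- function(h, bath, sink) {
  n <- h$n_sites
  basis <- diagonalize(h)
  rates <- secular_rates(basis, bath, sink)
  gen <- redfield_generator(rates, basis$eigenvalues, bath$temperature_K)
  C <- basis$eigenvectors
  p0 <- C[sink$donor, ]^2
  w0 <- as.vector(crossprod(gen$U, p0 / gen$d))
  back <- gen$U * gen$d                       # exciton x mode, row a = d_a U_a.
  acc_w <- as.vector(C[sink$acceptor, ]^2 %*% back)   # mode weights for rho_acc
  lam <- gen$lambda
  I0 <- sum(acc_w * w0 * (-1 / lam))
  I1 <- sum(acc_w * w0 * (1 / lam^2))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  amp <- C[sink$donor, pairs[, 1]] * C[sink$donor, pairs[, 2]]
  w_ab <- cm1_to_angfreq(basis$eigenvalues[pairs[, 1]] - basis$eigenvalues[pairs[, 2]])
  g_ab <- rates$dephasing_rates[pairs]
  macc <- C[sink$acceptor, pairs[, 1]] * C[sink$acceptor, pairs[, 2]]
  coh <- 2 * amp * macc
  I0 <- I0 + sum(coh * g_ab / (g_ab^2 + w_ab^2))
  I1 <- I1 + sum(coh * (g_ab^2 - w_ab^2) / (g_ab^2 + w_ab^2)^2)
  g_trap <- rate_ps_to_fs(sink$gamma_trap_ps)
  list(efficiency = g_trap * I0, transfer_time_ps = (I1 / I0) / 1000)
}
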