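test_that("diagonalize returns an ordered orthonormal exciton basis", {
  h <- sample_hamiltonian(dataset_ranges("FMO"), seed = 5)
  b <- diagonalize(h)
  expect_true(all(diff(b$eigenvalues) >= 0))
  expect_equal(crossprod(b$eigenvectors), diag(8), tolerance = 1e-12)
  expect_equal(b$eigenvectors %*% diag(b$eigenvalues) %*% t(b$eigenvectors),
               as.matrix(h), tolerance = 1e-9)
})

test_that("secular rates obey detailed balance exactly", {
  h <- sample_hamiltonian(dataset_ranges("FMO"), seed = 6)
  bath <- bath_parameters()
  rates <- secular_rates(diagonalize(h), bath, sink_parameters(acceptor = 3))
  k <- rates$population_rates
  E <- diagonalize(h)$eigenvalues
  kT <- eet_constants$boltzmann_cm1_K * bath$temperature_K
  for (a in 1:8) for (b in 1:8) if (a != b) {
    expect_equal(k[a, b] / k[b, a], exp((E[a] - E[b]) / kT), tolerance = 1e-10)
  }
  expect_true(all(k[row(k) != col(k)] > 0))
})

test_that("without sinks the Pauli dynamics relax to the Boltzmann state", {
  h <- sample_hamiltonian(dataset_ranges("RC"), seed = 7)
  bath <- bath_parameters()
  # effectively sink-free: negligible trap and loss
  sink <- sink_parameters(donor = 1, acceptor = 3, gamma_trap_ps = 1e-12,
                          gamma_loss_ps = 1e-12)
  basis <- diagonalize(h)
  rates <- secular_rates(basis, bath, sink)
  gen <- redfield_generator(rates, basis$eigenvalues, bath$temperature_K)
  p0 <- basis$eigenvectors[1, ]^2
  w0 <- crossprod(gen$U, p0 / gen$d)
  t_inf <- 5e7  # 50 ns
  p_inf <- as.vector((gen$U * gen$d) %*% (exp(gen$lambda * t_inf) * w0))
  kT <- eet_constants$boltzmann_cm1_K * bath$temperature_K
  boltz <- exp(-(basis$eigenvalues - min(basis$eigenvalues)) / kT)
  boltz <- boltz / sum(boltz)
  expect_lt(max(abs(p_inf / sum(p_inf) - boltz)), 1e-4)
})

test_that("trajectory statistics match the closed-form Redfield oracle", {
  h <- sample_hamiltonian(dataset_ranges("FMO"), seed = 8)
  bath <- bath_parameters()
  sink <- sink_parameters(donor = 1, acceptor = 3)
  oracle <- redfield_stats_closed_form(h, bath, sink)
  traj <- propagate_secular_redfield(h, bath, sink,
                                     grid = time_grid(t_max_fs = 4e5, dt_fs = 1,
                                                      store_every = 20),
                                     tail_tol = 1e-6)
  st <- transfer_statistics(traj, sink, tail_tol = 1e-6)
  expect_equal(st$transfer_time_ps, oracle$transfer_time_ps, tolerance = 1e-4)
  expect_equal(st$efficiency, oracle$efficiency, tolerance = 1e-4)
})

test_that("Redfield decay flux balances trapping plus loss after dephasing", {
  # The secular model traps from exciton populations, so the site-basis
  # ledger holds exactly only once the donor coherences have decayed.
  h <- sample_hamiltonian(dataset_ranges("FMO"), seed = 9)
  sink <- sink_parameters(donor = 1, acceptor = 3)
  traj <- propagate_secular_redfield(h, bath_parameters(), sink,
                                     grid = time_grid(t_max_fs = 1e5, dt_fs = 1,
                                                      store_every = 2),
                                     tail_tol = 0)
  t <- traj$time_fs
  late <- which(t > 1e4)            # > 10 ps
  i <- late[late > 1 & late < nrow(traj)]
  dtot <- (traj$total_excited[i + 1] - traj$total_excited[i - 1]) /
    (t[i + 1] - t[i - 1])
  flux <- -1e-3 * traj$pop_3[i] - 4e-6 * traj$total_excited[i]
  expect_lt(max(abs(dtot - flux)), 1e-7)
  expect_true(all(diff(traj$total_excited) <= 1e-8))
})

test_that("Redfield starts from the pure donor site state", {
  h <- sample_hamiltonian(dataset_ranges("CP43"), seed = 10)
  sink <- sink_parameters(donor = 2, acceptor = 5)
  traj <- propagate_secular_redfield(h, bath_parameters(), sink,
                                     grid = time_grid(t_max_fs = 1000, dt_fs = 1,
                                                      store_every = 10))
  expect_equal(traj$pop_2[1], 1, tolerance = 1e-10)
  expect_equal(sum(as.matrix(traj[1, paste0("pop_", 1:21)])), 1,
               tolerance = 1e-10)
})
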