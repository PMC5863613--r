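test_that("hierarchy enumeration has the binomial count and consistent maps", {
  h0 <- build_hierarchy(8, 0)
  expect_equal(h0$n_ados, 1)
  h4 <- build_hierarchy(8, 4)
  expect_equal(h4$n_ados, choose(12, 4))
  expect_true(all(h4$indices[1, ] == 0))
  # raising then lowering returns to the same ADO wherever both exist
  for (m in 1:8) {
    has_up <- which(h4$up[, m] >= 0)
    back <- h4$down[h4$up[has_up, m] + 1, m]
    expect_equal(back, has_up - 1L)
  }
  # depth-row sums never exceed the truncation
  expect_true(all(rowSums(h4$indices) <= 4))
  expect_error(build_hierarchy(24, 10, max_ados = 1e5), "cap")
})

test_that("lambda -> 0 reduces HEOM to the unitary-sink engine exactly", {
  h <- sample_hamiltonian(dataset_ranges("FMO"), seed = 31)
  sink <- sink_parameters(donor = 1, acceptor = 3)
  bath0 <- bath_parameters(lambda_cm1 = 0)
  grid <- time_grid(t_max_fs = 5000, dt_fs = 1, store_every = 10)
  th <- propagate_heom(h, bath0, sink, depth = 2, grid = grid, tail_tol = 0)
  tu <- propagate_unitary_sink(h, sink, grid = grid, tail_tol = 0)
  expect_lt(max(abs(as.matrix(th[, paste0("pop_", 1:8)]) -
                    as.matrix(tu[, paste0("pop_", 1:8)]))), 1e-6)
})

test_that("a detuned dimer matches the naive-hierarchy oracle to 1e-6", {
  hm <- matrix(c(100, 60, 60, 0), 2, 2)
  h <- hamiltonian_from_matrix(hm)
  bath <- bath_parameters()
  sink <- sink_parameters(donor = 1, acceptor = 2)
  grid <- time_grid(t_max_fs = 400, dt_fs = 2, store_every = 5)
  tr <- propagate_heom(h, bath, sink, depth = 8, grid = grid, tail_tol = 0)
  nv <- naive_heom(hm, bath, sink, depth = 8, dt = 2, t_max = 400)
  stored <- seq(1, nrow(nv$pops), by = 5)
  expect_lt(max(abs(as.matrix(tr[, c("pop_1", "pop_2")]) - nv$pops[stored, ])),
            1e-6)
})

test_that("the time-local correction toggle changes the dynamics", {
  h <- hamiltonian_from_matrix(matrix(c(100, 60, 60, 0), 2, 2))
  bath <- bath_parameters()
  sink <- sink_parameters(donor = 1, acceptor = 2)
  grid <- time_grid(t_max_fs = 400, dt_fs = 2, store_every = 10)
  t1 <- propagate_heom(h, bath, sink, depth = 2, grid = grid,
                       lt_correction = TRUE, tail_tol = 0)
  t2 <- propagate_heom(h, bath, sink, depth = 2, grid = grid,
                       lt_correction = FALSE, tail_tol = 0)
  expect_gt(max(abs(t1$pop_2 - t2$pop_2)), 1e-6)
})

test_that("HEOM conserves the probability ledger", {
  h <- sample_hamiltonian(dataset_ranges("FMO"), seed = 22)
  sink <- sink_parameters(donor = 1, acceptor = 3)
  traj <- propagate_heom(h, bath_parameters(), sink, depth = 2,
                         grid = time_grid(t_max_fs = 3e4, dt_fs = 2,
                                          store_every = 2))
  t <- traj$time_fs
  cum2 <- function(y) c(0, cumsum(diff(t) * (y[-length(y)] + y[-1]) / 2))
  ledger <- traj$total_excited + (1 / 1000) * cum2(traj$pop_3) +
    (1 / 250 / 1000) * cum2(traj$total_excited)
  expect_lt(max(abs(ledger - 1)), 1e-5)
})

test_that("converged_transfer_time reports its depth sequence and errors out", {
  h <- hamiltonian_from_matrix(matrix(c(150, 70, 70, 0), 2, 2))
  sink <- sink_parameters(donor = 1, acceptor = 2)
  res <- converged_transfer_time(h, bath_parameters(), sink,
                                 grid = fast_grid(), depth_start = 2)
  expect_s3_class(res, "eet_converged_stats")
  expect_true(res$converged)
  expect_equal(res$depth_sequence[length(res$depth_sequence)], res$depth)
  expect_lt(abs(diff(utils::tail(res$tbar_sequence, 2))) /
              res$stats$transfer_time_ps, 0.01)
  # an impossible tolerance triggers the convergence error class
  expect_error(
    converged_transfer_time(h, bath_parameters(), sink, tolerance = 1e-12,
                            depth_start = 0, depth_max = 2,
                            grid = time_grid(t_max_fs = 2000, dt_fs = 4,
                                             store_every = 10)),
    class = "eet_convergence_error")
})
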