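#' Build the triangular HEOM hierarchy
#'
#' Enumerates all auxiliary density operator (ADO) indices
#' `n = (n_1, ..., n_N)` with `sum(n) <= depth` (one Drude mode per site)
#' and precomputes, for every index and site, the position of the raised
#' and lowered neighbour. The number of ADOs is `choose(N + depth, depth)`.
#'
#' @param n_sites Number of pigments.
#' @param depth Truncation depth (>= 0).
#' @param max_ados Resource cap on the hierarchy size.
#' @return A list with `indices` (ADO x site integer matrix, physical ADO
#'   first), `up`/`down` (0-based neighbour positions, -1 where absent),
#'   `n_ados` and `depth`.
#' @export
build_hierarchy <- function(n_sites, depth, max_ados = 5e5) {
  stopifnot(n_sites >= 1, depth >= 0)
  count <- choose(n_sites + depth, depth)
  if (count > max_ados)
    stop(sprintf("hierarchy would hold %.0f ADOs, above the cap of %g", count, max_ados),
         call. = FALSE)
  gen <- function(n, d_max) {
    if (n == 1) return(matrix(0:d_max, ncol = 1))
    sub <- gen(n - 1, d_max)
    rs <- rowSums(sub)
    do.call(rbind, lapply(0:d_max, function(v)
      cbind(v, sub[rs <= d_max - v, , drop = FALSE])))
  }
  idx <- gen(n_sites, depth)
  storage.mode(idx) <- "integer"
  ord <- do.call(order, c(list(rowSums(idx)), lapply(seq_len(n_sites), function(j) idx[, j])))
  idx <- idx[ord, , drop = FALSE]
  dimnames(idx) <- NULL
  key <- apply(idx, 1, paste, collapse = ",")
  K <- nrow(idx)
  up <- matrix(-1L, K, n_sites)
  down <- matrix(-1L, K, n_sites)
  for (m in seq_len(n_sites)) {
    ku <- idx; ku[, m] <- ku[, m] + 1L
    up[, m] <- match(apply(ku, 1, paste, collapse = ","), key, nomatch = 0L) - 1L
    kd <- idx; kd[, m] <- kd[, m] - 1L
    has_dn <- idx[, m] > 0L
    down[has_dn, m] <-
      match(apply(kd[has_dn, , drop = FALSE], 1, paste, collapse = ","), key) - 1L
  }
  list(indices = idx, up = up, down = down, n_ados = K, depth = depth)
}

# Drude expansion coefficient and time-local correction strength, rad/fs.
# c = lambda * nu * (cot(beta*nu/2) - i); Delta = lambda * (2/(beta*nu) - cot(beta*nu/2)).
heom_bath_coefficients <- function(bath) {
  lam <- cm1_to_angfreq(bath$lambda_cm1)
  nu <- cm1_to_angfreq(bath$nu_cm1)
  kT <- cm1_to_angfreq(eet_constants$boltzmann_cm1_K * bath$temperature_K)
  x <- nu / (2 * kT)                      # beta * nu / 2
  cot_x <- 1 / tan(x)
  list(c_coef = complex(real = lam * nu * cot_x, imaginary = -lam * nu),
       delta = lam * (1 / x - cot_x), nu = nu, beta_nu = 2 * x)
}

#' Propagate exciton dynamics with the hierarchical equations of motion
#'
#' Numerically exact reference engine: scaled HEOM for a Drude-Lorentz bath
#' with a single exponential mode per site (high-temperature truncation)
#' and, by default, the time-local low-temperature correction for the
#' dropped Matsubara terms. Trapping and loss act through the
#' anti-Hermitian [effective_hamiltonian()] applied to every ADO.
#' Integration is fixed-step RK4; on a population overshoot the step is
#' halved automatically, once.
#'
#' @param h A [frenkel_hamiltonian()].
#' @param bath A [bath_parameters()].
#' @param sink A [sink_parameters()].
#' @param depth Hierarchy truncation depth.
#' @param grid A [time_grid()]; default 2 fs steps, storing every 10.
#' @param lt_correction Enable the time-local Matsubara correction.
#' @param tail_tol Stop once the excited population falls below this.
#' @param hierarchy Optional precomputed [build_hierarchy()] result.
#' @return An `eet_trajectory`.
#' @export
propagate_heom <- function(h, bath, sink, depth = 6,
                           grid = time_grid(dt_fs = 2, store_every = 10),
                           lt_correction = TRUE, tail_tol = 1e-4,
                           hierarchy = NULL) {
  stopifnot(inherits(h, "frenkel_hamiltonian"), inherits(bath, "bath_parameters"),
            inherits(sink, "sink_parameters"), inherits(grid, "time_grid"))
  n <- h$n_sites
  cf <- heom_bath_coefficients(bath)
  if (cf$beta_nu > 2)
    warning("high-temperature approximation questionable: k_B T < h nu / 2",
            call. = FALSE)
  hier <- if (is.null(hierarchy)) build_hierarchy(n, depth) else hierarchy
  stopifnot(ncol(hier$indices) == n)

  Heff <- (effective_hamiltonian(h, sink) - diag(mean(h$energies), n)) *
    eet_constants$cm1_to_radfs
  absc <- Mod(cf$c_coef)
  if (absc > 0) {
    s_up <- sqrt((hier$indices + 1) * absc)
    s_dn <- sqrt(hier$indices / absc)
  } else {
    s_up <- matrix(0, hier$n_ados, n)
    s_dn <- matrix(0, hier$n_ados, n)
  }
  damp <- rowSums(hier$indices) * cf$nu
  delta <- if (lt_correction) cf$delta else 0
  rho0 <- matrix(0 + 0i, n, n)
  rho0[sink$donor, sink$donor] <- 1 + 0i

  run <- function(dt) {
    n_steps <- ceiling(grid$t_max_fs / dt)
    cpp_propagate_heom(Heff, hier$up, hier$down, damp, s_up, s_dn,
                       cf$c_coef, delta, rho0, dt, n_steps,
                       grid$store_every, tail_tol, 1e3)
  }
  res <- run(grid$dt_fs)
  if (res$unstable) res <- run(grid$dt_fs / 2)
  if (res$unstable)
    stop("HEOM propagation unstable even after halving dt; reduce dt below ",
         grid$dt_fs / 2, " fs", call. = FALSE)
  if (res$diverged)
    stop("HEOM hierarchy diverged (ADO norm above cap); increase depth or reduce dt",
         call. = FALSE)
  traj <- new_trajectory(res$times, res$pops, res$total, sink, "heom")
  attr(traj, "depth") <- depth
  traj
}

#' Depth-converged HEOM transfer statistics
#'
#' Runs the HEOM engine at increasing truncation depths
#' (`depth_start, depth_start + depth_step, ...`) until the mean transfer
#' time changes by less than `tolerance` (relative), and returns the last
#' result together with the depth sequence.
#'
#' @inheritParams propagate_heom
#' @param tolerance Relative tolerance on the transfer time (default 1%).
#' @param depth_start,depth_step,depth_max Depth sweep schedule.
#' @return An `eet_converged_stats` object: the final `stats`
#'   ([transfer_statistics()] result), `depth`, `depth_sequence`,
#'   `tbar_sequence` and `converged`.
#' @export
converged_transfer_time <- function(h, bath, sink, tolerance = 0.01,
                                    depth_start = 2, depth_step = 2, depth_max = 12,
                                    grid = time_grid(dt_fs = 2, store_every = 10),
                                    lt_correction = TRUE, tail_tol = 1e-4) {
  stopifnot(tolerance > 0)
  depths <- seq(depth_start, depth_max, by = depth_step)
  tbars <- numeric(0)
  stats <- NULL
  for (i in seq_along(depths)) {
    traj <- propagate_heom(h, bath, sink, depth = depths[i], grid = grid,
                           lt_correction = lt_correction, tail_tol = tail_tol)
    stats <- transfer_statistics(traj, sink, tail_tol = tail_tol)
    tbars <- c(tbars, stats$transfer_time_ps)
    if (i > 1 && abs(tbars[i] - tbars[i - 1]) / abs(tbars[i]) < tolerance) {
      return(structure(list(stats = stats, depth = depths[i],
                            depth_sequence = depths[seq_len(i)],
                            tbar_sequence = tbars, converged = TRUE),
                       class = "eet_converged_stats"))
    }
  }
  rlang::abort(
    sprintf("HEOM transfer time not converged to %.2g%% by depth %d",
            100 * tolerance, depth_max),
    class = "eet_convergence_error",
    depth_sequence = depths, tbar_sequence = tbars, partial = stats)
}

#' @export
print.eet_converged_stats <- function(x, ...) {
  cat(sprintf("<eet_converged_stats> converged at depth %d\n", x$depth))
  cat("  t_bar (ps) by depth:",
      paste(sprintf("%d: %.4f", x$depth_sequence, x$tbar_sequence), collapse = ", "), "\n")
  print(x$stats)
  invisible(x)
}
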