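#' Construct a population trajectory
#'
#' Shared result container of all propagation engines: a tibble with one
#' row per stored time point, columns `time_fs`, `pop_<site>` for each
#' pigment (diagonal of the reduced density matrix in the site basis) and
#' `total_excited` (its trace).
#'
#' @param times_fs Strictly increasing time grid starting at 0 (fs).
#' @param populations Matrix, time x site.
#' @param total_excited Trace of the excited-state density matrix.
#' @param sink The [sink_parameters()] used.
#' @param engine Engine tag, e.g. `"heom"`, `"redfield"`, `"unitary"`.
#' @return A tibble of class `eet_trajectory` carrying `sink` and `engine`
#'   attributes.
#' @export
new_trajectory <- function(times_fs, populations, total_excited, sink, engine) {
  populations <- as.matrix(populations)
  times_fs <- as.vector(times_fs)
  total_excited <- as.vector(total_excited)
  stopifnot(length(times_fs) == nrow(populations),
            length(total_excited) == nrow(populations),
            times_fs[1] == 0, !is.unsorted(times_fs, strictly = TRUE))
  colnames(populations) <- paste0("pop_", seq_len(ncol(populations)))
  out <- tibble::as_tibble(populations)
  out <- tibble::add_column(out, time_fs = times_fs, .before = 1)
  out$total_excited <- total_excited
  class(out) <- c("eet_trajectory", class(out))
  attr(out, "sink") <- sink
  attr(out, "engine") <- engine
  out
}

trajectory_populations <- function(traj) {
  as.matrix(traj[grep("^pop_", names(traj), value = TRUE)])
}

#' Plot a population trajectory
#'
#' Site populations and total excited-state population versus time.
#'
#' @param object An `eet_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eet_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = -"time_fs",
                              names_to = "state", values_to = "population")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_fs / 1000,
                                     y = .data$population,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "population",
                  title = paste("engine:", attr(object, "engine")))
}

# Exponential tail fit on the last `frac` of the stored grid.
# Returns list(ok, rate_fs, value_end): rho(t) ~ value_end * exp(-rate*(t-T)).
fit_exponential_tail <- function(times, values, frac = 0.2) {
  n <- length(times)
  i0 <- max(1L, n - max(4L, ceiling(frac * n)) + 1L)
  t <- times[i0:n]; v <- values[i0:n]
  keep <- v > 0
  if (sum(keep) < 4) return(list(ok = FALSE, rate_fs = NA_real_, value_end = NA_real_))
  fit <- stats::lm.fit(cbind(1, t[keep]), log(v[keep]))
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= 0)
    return(list(ok = FALSE, rate_fs = NA_real_, value_end = NA_real_))
  list(ok = TRUE, rate_fs = -slope,
       value_end = exp(fit$coefficients[1] + slope * times[n]))
}

# composite trapezoid of y and t*y on a (possibly non-uniform) grid
trapezoid_moments <- function(t, y) {
  dt <- diff(t)
  i0 <- sum(dt * (y[-length(y)] + y[-1]) / 2)
  ty <- t * y
  i1 <- sum(dt * (ty[-length(ty)] + ty[-1]) / 2)
  c(i0 = i0, i1 = i1)
}

#' Transfer efficiency and mean transfer time from a trajectory
#'
#' The efficiency is the total probability captured by the trap,
#' `eta = Gamma_trap * integral of rho_acc(t) dt`, and the mean transfer
#' time is the first moment of the trapping flux,
#' `tbar = (Gamma_trap / eta) * integral of t * rho_acc(t) dt`, reported in
#' ps. Integrals use the composite trapezoid rule on the stored grid plus
#' an exponential-tail correction fitted by linear regression on
#' `log rho_acc` over the final 20 percent of the grid. The fraction lost
#' to exciton decay is computed the same way from the total excited
#' population.
#'
#' @param traj An `eet_trajectory` (see [new_trajectory()]).
#' @param sink The [sink_parameters()]; defaults to the trajectory's own.
#' @param tail_tol If the excited population remaining at the horizon
#'   exceeds this and the tail fit fails, a convergence warning is flagged.
#' @return An `eet_transfer_stats` object: `efficiency`, `transfer_time_ps`,
#'   `tail_fraction`, `loss_fraction`, `tail_fit_ok`, `converged`.
#' @export
transfer_statistics <- function(traj, sink = attr(traj, "sink"), tail_tol = 1e-4) {
  stopifnot(inherits(traj, "eet_trajectory"), inherits(sink, "sink_parameters"))
  t <- traj$time_fs
  rho_acc <- traj[[paste0("pop_", sink$acceptor)]]
  if (is.null(rho_acc)) stop("acceptor index exceeds trajectory sites", call. = FALSE)
  total <- traj$total_excited
  g_trap <- rate_ps_to_fs(sink$gamma_trap_ps)
  g_loss <- rate_ps_to_fs(sink$gamma_loss_ps)

  m_acc <- trapezoid_moments(t, rho_acc)
  tail <- fit_exponential_tail(t, rho_acc)
  Tend <- t[length(t)]
  if (tail$ok) {
    k <- tail$rate_fs
    m_acc["i0"] <- m_acc["i0"] + tail$value_end / k
    m_acc["i1"] <- m_acc["i1"] + tail$value_end * (Tend + 1 / k) / k
  }

  m_tot <- trapezoid_moments(t, total)
  tail_tot <- fit_exponential_tail(t, total)
  if (tail_tot$ok) m_tot["i0"] <- m_tot["i0"] + tail_tot$value_end / tail_tot$rate_fs

  eta <- unname(g_trap * m_acc["i0"])
  if (eta < 1e-12)
    stop("no transfer: acceptor population integral is zero, transfer time undefined",
         call. = FALSE)
  tbar_fs <- unname(m_acc["i1"] / m_acc["i0"])
  tail_fraction <- total[length(total)]
  converged <- tail_fraction < tail_tol || tail$ok
  if (!converged)
    warning("trajectory not converged: tail fraction ", signif(tail_fraction, 3),
            " above tolerance and tail fit failed", call. = FALSE)
  structure(
    list(efficiency = eta,
         transfer_time_ps = tbar_fs / 1000,
         tail_fraction = tail_fraction,
         loss_fraction = unname(g_loss * m_tot["i0"]),
         tail_fit_ok = tail$ok,
         converged = converged),
    class = "eet_transfer_stats"
  )
}

#' @export
print.eet_transfer_stats <- function(x, ...) {
  cat(sprintf("<eet_transfer_stats> efficiency = %.5f, transfer time = %.4f ps\n",
              x$efficiency, x$transfer_time_ps))
  cat(sprintf("  tail fraction %.3g, loss fraction %.4f, converged: %s\n",
              x$tail_fraction, x$loss_fraction, x$converged))
  invisible(x)
}

#' @export
tidy.eet_transfer_stats <- function(x, ...) {
  tibble::tibble(efficiency = x$efficiency,
                 transfer_time_ps = x$transfer_time_ps,
                 tail_fraction = x$tail_fraction,
                 loss_fraction = x$loss_fraction,
                 converged = x$converged)
}

#' Write transfer statistics to JSON
#'
#' @param stats An `eet_transfer_stats`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transfer_stats <- function(stats, path) {
  jsonlite::write_json(
    list(efficiency = stats$efficiency,
         transfer_time_ps = stats$transfer_time_ps,
         tail_fraction = stats$tail_fraction),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Time grid specification for fixed-step propagation
#'
#' @param t_max_fs Propagation horizon in fs (default 200 ps).
#' @param dt_fs Integrator step in fs.
#' @param store_every Store every k-th step.
#' @return A `time_grid` object.
#' @export
time_grid <- function(t_max_fs = 2e5, dt_fs = 1, store_every = 20) {
  stopifnot(t_max_fs > 0, dt_fs > 0, store_every >= 1)
  structure(list(t_max_fs = t_max_fs, dt_fs = dt_fs,
                 store_every = as.integer(store_every)),
            class = "time_grid")
}
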