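# Independent oracles used across test files. These deliberately avoid the
# package's own code paths (no scaled hierarchy, no closed-form propagator)
# so that agreement is meaningful.

# Unscaled, plain-R HEOM integrator over a dense list of ADOs; brute-force
# index bookkeeping and classical RK4.
naive_heom <- function(H_cm, bath, sink, depth, dt, t_max, lt_correction = TRUE) {
  n <- nrow(H_cm)
  conv <- 2 * pi * 2.99792458e-5
  lam <- bath$lambda_cm1 * conv; nu <- bath$nu_cm1 * conv
  kT <- 0.6950348 * bath$temperature_K * conv
  x <- nu / (2 * kT); cotx <- 1 / tan(x)
  cc <- complex(real = lam * nu * cotx, imaginary = -lam * nu)
  delta <- if (lt_correction) lam * (1 / x - cotx) else 0
  gt <- sink$gamma_trap_ps / 1000; gl <- sink$gamma_loss_ps / 1000
  Heff <- (H_cm - diag(mean(diag(H_cm)), n)) * conv + 0i
  Heff[sink$acceptor, sink$acceptor] <- Heff[sink$acceptor, sink$acceptor] - 1i * gt / 2
  diag(Heff) <- diag(Heff) - 1i * gl / 2
  HeffH <- Conj(t(Heff))
  idx <- list()
  rec <- function(pref, rem, slots) {
    if (slots == 0) { idx[[length(idx) + 1]] <<- pref; return(invisible()) }
    for (v in 0:rem) rec(c(pref, v), rem - v, slots - 1)
  }
  rec(integer(0), depth, n)
  key <- sapply(idx, paste, collapse = "_")
  pos <- function(v) { m <- match(paste(v, collapse = "_"), key); if (is.na(m)) 0 else m }
  K <- length(idx)
  Vs <- lapply(1:n, function(m) { M <- matrix(0, n, n); M[m, m] <- 1; M })
  deriv <- function(A) {
    dA <- vector("list", K)
    for (k in 1:K) {
      nk <- idx[[k]]
      D <- -1i * (Heff %*% A[[k]] - A[[k]] %*% HeffH) - sum(nk) * nu * A[[k]]
      for (m in 1:n) {
        Vm <- Vs[[m]]
        if (delta != 0)
          D <- D - delta * (Vm %*% Vm %*% A[[k]] - 2 * Vm %*% A[[k]] %*% Vm +
                            A[[k]] %*% Vm %*% Vm)
        upv <- nk; upv[m] <- upv[m] + 1; ku <- pos(upv)
        if (ku > 0) D <- D - 1i * (Vm %*% A[[ku]] - A[[ku]] %*% Vm)
        if (nk[m] > 0) {
          dnv <- nk; dnv[m] <- dnv[m] - 1; kd <- pos(dnv)
          D <- D - 1i * nk[m] * (cc * Vm %*% A[[kd]] - Conj(cc) * A[[kd]] %*% Vm)
        }
      }
      dA[[k]] <- D
    }
    dA
  }
  A <- lapply(1:K, function(k) matrix(0 + 0i, n, n))
  A[[1]][sink$donor, sink$donor] <- 1 + 0i
  stopifnot(all(idx[[1]] == 0))
  nst <- ceiling(t_max / dt)
  out_t <- numeric(nst + 1); out_p <- matrix(0, nst + 1, n)
  saxpy <- function(A, B, s) mapply(function(a, b) a + s * b, A, B, SIMPLIFY = FALSE)
  out_t[1] <- 0; out_p[1, ] <- Re(diag(A[[1]]))
  for (s in 1:nst) {
    k1 <- deriv(A)
    k2 <- deriv(saxpy(A, k1, dt / 2))
    k3 <- deriv(saxpy(A, k2, dt / 2))
    k4 <- deriv(saxpy(A, k3, dt))
    for (k in 1:K)
      A[[k]] <- A[[k]] + dt / 6 * (k1[[k]] + 2 * k2[[k]] + 2 * k3[[k]] + k4[[k]])
    out_t[s + 1] <- s * dt; out_p[s + 1, ] <- Re(diag(A[[1]]))
  }
  list(times = out_t, pops = out_p)
}

# Analytic transfer statistics for a monoexponential acceptor population
# rho_acc(t) = a * exp(-k t): eta = gt * a / k, tbar = 1/k.
mono_trajectory <- function(a, k_fs, sink, t_max = 2e4, by = 10) {
  t <- seq(0, t_max, by = by)
  rho <- a * exp(-k_fs * t)
  new_trajectory(t, cbind(rho, rho), 2 * rho, sink, "oracle")
}

# Exhaustive max-min dispersion optimum over all k-subsets of small pools.
brute_force_dispersion <- function(z, k) {
  best <- -Inf
  for (s in utils::combn(nrow(z), k, simplify = FALSE)) {
    d <- min(stats::dist(z[s, , drop = FALSE]))
    if (d > best) best <- d
  }
  best
}

bio_fmo_hamiltonian <- function() {
  read_hamiltonian(system.file("extdata", "fmo_8site_cm1.txt",
                               package = "excitonet"))
}

fast_grid <- function(dt_fs = 4, store_every = 5, t_max_fs = 2e5) {
  time_grid(t_max_fs = t_max_fs, dt_fs = dt_fs, store_every = store_every)
}
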