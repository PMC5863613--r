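#' Hyperparameter search space for the surrogate
#'
#' Six dimensions: learning rate mu (log-uniform), L2 strength lambda_reg
#' (log-uniform), number of hidden layers, neurons per layer, the hidden
#' activation (one of five, applied to every hidden layer) and the number
#' of training points.
#'
#' @param mu,l2 Length-2 ranges (log-uniform).
#' @param layers,neurons,n_train Length-2 integer ranges.
#' @param activations Candidate activation names.
#' @return An `eet_hpo_space` object.
#' @export
hyperparameter_space <- function(mu = c(1e-5, 1e-2), l2 = c(1e-8, 1e-2),
                                 layers = c(1L, 5L), neurons = c(16L, 1024L),
                                 activations = c("rectifier", "tanh", "logistic",
                                                 "softsign", "softplus"),
                                 n_train = c(500L, 6000L)) {
  stopifnot(all(mu > 0), all(l2 > 0), layers[1] >= 1, neurons[1] >= 1,
            n_train[1] >= 1, length(activations) >= 1)
  structure(list(mu = sort(mu), l2 = sort(l2), layers = sort(as.integer(layers)),
                 neurons = sort(as.integer(neurons)),
                 activations = activations,
                 n_train = sort(as.integer(n_train))),
            class = "eet_hpo_space")
}

# Encode a config into [0,1]^d: log10(mu), log10(l2), layers, log2(neurons),
# n_train (all min-max scaled) plus a one-hot block for the activation.
hpo_encode <- function(space, config) {
  u <- function(x, lo, hi) if (hi > lo) (x - lo) / (hi - lo) else 0.5
  onehot <- as.numeric(space$activations == config$activation)
  c(u(log10(config$mu), log10(space$mu[1]), log10(space$mu[2])),
    u(log10(config$l2), log10(space$l2[1]), log10(space$l2[2])),
    u(config$layers, space$layers[1], space$layers[2]),
    u(log2(config$neurons), log2(space$neurons[1]), log2(space$neurons[2])),
    u(config$n_train, space$n_train[1], space$n_train[2]),
    onehot)
}

hpo_decode <- function(space, v) {
  iu <- function(u, lo, hi) lo + u * (hi - lo)
  a <- space$activations[which.max(v[-(1:5)])]
  list(mu = 10^iu(v[1], log10(space$mu[1]), log10(space$mu[2])),
       l2 = 10^iu(v[2], log10(space$l2[1]), log10(space$l2[2])),
       layers = as.integer(round(iu(v[3], space$layers[1], space$layers[2]))),
       neurons = as.integer(round(2^iu(v[4], log2(space$neurons[1]),
                                       log2(space$neurons[2])))),
       n_train = as.integer(round(iu(v[5], space$n_train[1], space$n_train[2]))),
       activation = a)
}

hpo_sample_raw <- function(space, n, seed) {
  d <- 5 + length(space$activations)
  if (requireNamespace("lhs", quietly = TRUE)) {
    withr::with_seed(seed, lhs::randomLHS(n, d))
  } else {
    withr::with_seed(seed, matrix(stats::runif(n * d), n, d))
  }
}

# Gaussian-process regression with a squared-exponential kernel on the
# encoded unit cube; observations are standardized, the lengthscale is
# picked from a small grid by marginal likelihood.
gp_fit <- function(X, y) {
  ys <- (y - mean(y)) / max(stats::sd(y), 1e-12)
  d2 <- as.matrix(stats::dist(X))^2
  best <- NULL
  for (ell in c(0.1, 0.2, 0.5, 1, 2)) {
    K <- exp(-d2 / (2 * ell^2)) + diag(1e-6 + 1e-4, nrow(X))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    ll <- -0.5 * sum(ys * alpha) - sum(log(diag(ch)))
    if (is.null(best) || ll > best$ll)
      best <- list(ll = ll, ell = ell, ch = ch, alpha = alpha)
  }
  c(best, list(X = X, y_mean = mean(y), y_sd = max(stats::sd(y), 1e-12)))
}

gp_predict <- function(gp, Xnew) {
  d2 <- outer(rowSums(Xnew^2), rowSums(gp$X^2), "+") - 2 * Xnew %*% t(gp$X)
  Ks <- exp(-pmax(d2, 0) / (2 * gp$ell^2))
  mu <- as.vector(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$ch), t(Ks))
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = gp$y_mean + gp$y_sd * mu, sd = gp$y_sd * sqrt(s2))
}

expected_improvement <- function(mu, sd, best) {
  z <- (best - mu) / sd
  (best - mu) * stats::pnorm(z) + sd * stats::dnorm(z)
}

#' Bayesian hyperparameter optimization
#'
#' Minimizes `objective(config)` (e.g. validation mean relative absolute
#' error) over a [hyperparameter_space()]. Starts from 5 seeded
#' quasi-random configurations, then either fits a Gaussian-process
#' surrogate with expected-improvement acquisition (`method = "gp"`,
#' maximized over a seeded candidate pool) or falls back to pure random
#' search (`method = "random"`). A failing objective is logged, penalized
#' with a large finite value, and optimization continues. The full trace
#' is returned and deterministic for a given seed and budget.
#'
#' @param objective Function taking a config list (`mu`, `l2`, `layers`,
#'   `neurons`, `n_train`, `activation`) and returning a scalar to
#'   minimize.
#' @param space A [hyperparameter_space()].
#' @param budget Total number of objective evaluations (>= 2).
#' @param seed Integer seed.
#' @param method `"gp"` or `"random"`.
#' @param n_initial Size of the quasi-random initial design (default 5).
#' @param penalty Value recorded for failing configurations.
#' @return An `eet_hpo_result`: `best` config, `best_value`, and a `trace`
#'   tibble (iteration, config columns, objective, running best, failure
#'   flag and message).
#' @export
bayes_optimize <- function(objective, space, budget, seed = 1,
                           method = c("gp", "random"), n_initial = 5,
                           penalty = 1e6) {
  stopifnot(inherits(space, "eet_hpo_space"), budget >= 2)
  method <- match.arg(method)
  n_initial <- min(n_initial, budget)
  X <- hpo_sample_raw(space, n_initial, seed)
  rows <- list(); y <- numeric(0)
  evaluate <- function(v, it) {
    cfg <- hpo_decode(space, v)
    res <- tryCatch(objective(cfg), error = function(e) e)
    failed <- inherits(res, "error") || !is.finite(res)
    val <- if (failed) penalty else res
    rows[[it]] <<- tibble::tibble(
      iteration = it, mu = cfg$mu, l2 = cfg$l2, layers = cfg$layers,
      neurons = cfg$neurons, n_train = cfg$n_train, activation = cfg$activation,
      objective = val, failed = failed,
      message = if (inherits(res, "error")) conditionMessage(res) else NA_character_)
    val
  }
  for (i in seq_len(n_initial)) y[i] <- evaluate(X[i, ], i)

  it <- n_initial
  while (it < budget) {
    it <- it + 1
    cand <- hpo_sample_raw(space, 512, seed + 1000 + it)
    v <- if (method == "random") {
      cand[1, ]
    } else {
      gp <- gp_fit(X, y)
      if (is.null(gp$ch)) cand[1, ] else {
        pr <- gp_predict(gp, cand)
        ei <- expected_improvement(pr$mean, pr$sd, min(y))
        cand[which.max(ei), ]
      }
    }
    X <- rbind(X, v)
    y[it] <- evaluate(v, it)
  }
  trace <- dplyr::bind_rows(rows)
  trace$best_so_far <- cummin(trace$objective)
  best_i <- which.min(trace$objective)
  structure(list(best = hpo_decode(space, X[best_i, ]),
                 best_value = trace$objective[best_i],
                 trace = trace, method = method, seed = seed),
            class = "eet_hpo_result")
}

#' @export
print.eet_hpo_result <- function(x, ...) {
  b <- x$best
  cat(sprintf(paste0("<eet_hpo_result> %s, %d evaluations, best objective %.4g\n",
                     "  mu=%.3g l2=%.3g layers=%d neurons=%d n_train=%d activation=%s\n"),
              x$method, nrow(x$trace), x$best_value,
              b$mu, b$l2, b$layers, b$neurons, b$n_train, b$activation))
  invisible(x)
}
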