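#' Multi-layer perceptron architecture
#'
#' Fully connected network mapping a flattened Hamiltonian (length
#' `n_inputs`) to the pair (transfer time, efficiency). Hidden layers use
#' one of five activations; the output layer is always softplus so that
#' both predictions are strictly positive.
#'
#' @param n_inputs Input dimension (`n_sites^2`).
#' @param hidden Integer vector of hidden-layer widths.
#' @param activations Hidden activation name(s), recycled across layers:
#'   `"rectifier"`, `"tanh"`, `"logistic"`, `"softsign"` or `"softplus"`.
#' @param learning_rate Adam step size mu.
#' @param l2 L2 penalty lambda_reg on hidden-layer weights (the output
#'   layer is not penalized).
#' @return An `eet_mlp_architecture` object.
#' @export
mlp_architecture <- function(n_inputs, hidden = c(64, 64),
                             activations = "tanh",
                             learning_rate = 1e-3, l2 = 1e-6) {
  stopifnot(n_inputs >= 1, length(hidden) >= 1, all(hidden >= 1),
            learning_rate > 0, l2 >= 0)
  activations <- rep_len(activations, length(hidden))
  ok <- c("rectifier", "tanh", "logistic", "softsign", "softplus")
  if (!all(activations %in% ok))
    stop("activations must be among: ", paste(ok, collapse = ", "), call. = FALSE)
  structure(list(widths = c(n_inputs, hidden, 2L),
                 activations = c(activations, "softplus"),
                 learning_rate = learning_rate, l2 = l2),
            class = "eet_mlp_architecture")
}

mlp_activation <- function(name) {
  switch(name,
    rectifier = list(f = function(x) pmax(x, 0),
                     df = function(x, y) (x > 0) * 1),
    tanh      = list(f = tanh,
                     df = function(x, y) 1 - y^2),
    logistic  = list(f = stats::plogis,
                     df = function(x, y) y * (1 - y)),
    softsign  = list(f = function(x) x / (1 + abs(x)),
                     df = function(x, y) 1 / (1 + abs(x))^2),
    softplus  = list(f = function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30)))),
                     df = function(x, y) stats::plogis(x)),
    stop("unknown activation: ", name, call. = FALSE))
}

#' Initialize an MLP with variance-scaled random weights
#'
#' Weights are drawn from N(0, 2 / (fan_in + fan_out)) (Glorot scaling),
#' biases start at zero. Deterministic per seed.
#'
#' @param arch An [mlp_architecture()].
#' @param seed Integer seed.
#' @return An `eet_mlp` model (weights `W`, biases `b`, the architecture,
#'   and the seed).
#' @export
init_mlp <- function(arch, seed = 1) {
  stopifnot(inherits(arch, "eet_mlp_architecture"))
  w <- arch$widths
  L <- length(w) - 1
  model <- withr::with_seed(seed, {
    W <- lapply(seq_len(L), function(l)
      matrix(stats::rnorm(w[l] * w[l + 1], sd = sqrt(2 / (w[l] + w[l + 1]))),
             w[l], w[l + 1]))
    b <- lapply(seq_len(L), function(l) numeric(w[l + 1]))
    list(W = W, b = b)
  })
  structure(list(W = model$W, b = model$b, arch = arch, seed = seed,
                 scalers = NULL, history = NULL),
            class = "eet_mlp")
}

#' @export
print.eet_mlp <- function(x, ...) {
  cat(sprintf("<eet_mlp> widths %s; activations %s; %d parameters\n",
              paste(x$arch$widths, collapse = "-"),
              paste(x$arch$activations, collapse = ", "),
              sum(lengths(x$W)) + sum(lengths(x$b))))
  invisible(x)
}

# Forward pass on a batch (rows = records). Returns per-layer
# pre-activations z and activations a for backpropagation.
mlp_forward <- function(model, x) {
  L <- length(model$W)
  z <- vector("list", L); a <- vector("list", L + 1)
  a[[1]] <- x
  for (l in seq_len(L)) {
    act <- mlp_activation(model$arch$activations[l])
    z[[l]] <- a[[l]] %*% model$W[[l]] + rep(model$b[[l]], each = nrow(x))
    a[[l + 1]] <- act$f(z[[l]])
  }
  list(z = z, a = a, output = a[[L + 1]])
}

# Gradient of (MSE on scaled targets + l2 * sum(hidden W^2)) for one batch.
mlp_gradients <- function(model, x, y) {
  L <- length(model$W)
  fw <- mlp_forward(model, x)
  B <- nrow(x)
  gW <- vector("list", L); gb <- vector("list", L)
  # dLoss/d(output) for MSE averaged over batch and the 2 outputs
  delta <- 2 * (fw$output - y) / (B * ncol(y))
  for (l in rev(seq_len(L))) {
    act <- mlp_activation(model$arch$activations[l])
    delta <- delta * act$df(fw$z[[l]], fw$a[[l + 1]])
    gW[[l]] <- crossprod(fw$a[[l]], delta)
    if (l < L) gW[[l]] <- gW[[l]] + 2 * model$arch$l2 * model$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1) delta <- delta %*% t(model$W[[l]])
  }
  list(W = gW, b = gb, loss = mean((fw$output - y)^2))
}

#' Training configuration
#'
#' @param batch_size Records per stochastic-gradient batch (default 200).
#' @param max_epochs Hard cap on full passes over the training set.
#' @param patience Stop once validation error has increased over this many
#'   full consecutive epochs (default 3).
#' @param seed Seed controlling batch shuffling.
#' @return An `eet_training_config` list.
#' @export
training_config <- function(batch_size = 200, max_epochs = 200, patience = 3,
                            seed = 1) {
  stopifnot(batch_size >= 1, max_epochs >= 1, patience >= 1)
  structure(list(batch_size = batch_size, max_epochs = max_epochs,
                 patience = patience, seed = seed),
            class = "eet_training_config")
}

#' Train an MLP on scaled records with Adam and early stopping
#'
#' Minimizes mean squared error on scaler-transformed targets plus the L2
#' penalty on hidden weights, using Adam (beta1 = 0.9, beta2 = 0.999) over
#' shuffled mini-batches. After each epoch the mean relative absolute
#' error of the transfer-time prediction on the validation records
#' (original units) is evaluated; training stops once that error has risen
#' over `patience` full consecutive epochs, and the weights of the best
#' validation epoch are restored.
#'
#' @param model An [init_mlp()] model.
#' @param train,valid Disjoint record tibbles ([build_database()] schema).
#' @param scalers An [fit_scalers()] result fitted on `train` only.
#' @param config A [training_config()].
#' @return The trained `eet_mlp` with `scalers` attached and a `history`
#'   tibble (epoch, training loss, validation error %).
#' @export
train_mlp <- function(model, train, valid, scalers, config = training_config()) {
  stopifnot(inherits(model, "eet_mlp"), inherits(scalers, "eet_scalers"))
  x <- apply_scalers(scalers, features = feature_matrix(train))$features
  y <- apply_scalers(scalers, targets = cbind(train$transfer_time_ps,
                                              train$efficiency))$targets
  xv <- apply_scalers(scalers, features = feature_matrix(valid))$features
  tv <- valid$transfer_time_ps
  n <- nrow(x); L <- length(model$W)
  mu <- model$arch$learning_rate
  mW <- lapply(model$W, function(w) w * 0); vW <- mW
  mb <- lapply(model$b, function(b) b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0

  valid_error <- function(mod) {
    pred <- invert_scalers(scalers, targets = mlp_forward(mod, xv)$output)$targets
    100 * mean(abs(pred[, 1] - tv) / tv)
  }
  best <- list(W = model$W, b = model$b, err = Inf, epoch = 0)
  hist_epoch <- integer(0); hist_loss <- numeric(0); hist_verr <- numeric(0)
  increases <- 0; prev_err <- Inf

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        g <- mlp_gradients(model, x[idx, , drop = FALSE], y[idx, , drop = FALSE])
        if (!is.finite(g$loss))
          stop(sprintf("training diverged (non-finite loss) at learning rate %g", mu),
               call. = FALSE)
        losses <- c(losses, g$loss)
        step <- step + 1
        corr <- sqrt(1 - b2^step) / (1 - b1^step)
        for (l in seq_len(L)) {
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$W[[l]]
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$W[[l]]^2
          model$W[[l]] <- model$W[[l]] - mu * corr * mW[[l]] / (sqrt(vW[[l]]) + eps)
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$b[[l]]
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$b[[l]]^2
          model$b[[l]] <- model$b[[l]] - mu * corr * mb[[l]] / (sqrt(vb[[l]]) + eps)
        }
      }
      verr <- valid_error(model)
      hist_epoch <- c(hist_epoch, epoch)
      hist_loss <- c(hist_loss, mean(losses))
      hist_verr <- c(hist_verr, verr)
      if (verr < best$err) best <- list(W = model$W, b = model$b, err = verr,
                                        epoch = epoch)
      increases <- if (verr > prev_err) increases + 1 else 0
      prev_err <- verr
      if (increases >= config$patience) break
    }
  })
  model$W <- best$W
  model$b <- best$b
  model$scalers <- scalers
  model$history <- tibble::tibble(epoch = hist_epoch, train_loss = hist_loss,
                                  valid_error_pct = hist_verr,
                                  best = hist_epoch == best$epoch)
  model
}

#' Predict transfer properties from Hamiltonians
#'
#' @param object A trained `eet_mlp` (with scalers attached, or pass
#'   `scalers`).
#' @param hamiltonians A feature matrix (rows = flattened Hamiltonians), a
#'   records tibble with `h_*` columns, or a single [frenkel_hamiltonian()].
#' @param scalers Optional [fit_scalers()] override.
#' @param ... Unused.
#' @return A tibble with strictly positive `transfer_time_ps` and
#'   `efficiency`, one row per input.
#' @export
predict.eet_mlp <- function(object, hamiltonians, scalers = NULL, ...) {
  scalers <- scalers %||% object$scalers
  if (is.null(scalers)) stop("model has no scalers; pass `scalers`", call. = FALSE)
  x <- if (inherits(hamiltonians, "frenkel_hamiltonian")) {
    matrix(flatten_hamiltonian(hamiltonians), nrow = 1)
  } else if (is.matrix(hamiltonians)) hamiltonians else feature_matrix(hamiltonians)
  if (ncol(x) != object$arch$widths[1])
    stop(sprintf("feature length %d does not match model input %d",
                 ncol(x), object$arch$widths[1]), call. = FALSE)
  xs <- apply_scalers(scalers, features = x)$features
  out <- invert_scalers(scalers, targets = mlp_forward(object, xs)$output)$targets
  tibble::tibble(transfer_time_ps = out[, 1], efficiency = out[, 2])
}

#' Save or load an MLP model as JSON
#'
#' The file holds the architecture, seed, scalers, training history and all
#' weights at full precision, so a round trip reproduces predictions
#' exactly.
#'
#' @param model A trained or fresh `eet_mlp`.
#' @param path Output `.json` path.
#' @return `read_mlp()` returns the model; `write_mlp()` returns `path`
#'   invisibly.
#' @export
write_mlp <- function(model, path) {
  stopifnot(inherits(model, "eet_mlp"))
  payload <- list(
    architecture = unclass(model$arch),
    seed = model$seed,
    scalers = if (!is.null(model$scalers)) unclass(model$scalers),
    history = model$history,
    W = model$W, b = model$b)
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_mlp
#' @export
read_mlp <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  arch <- structure(list(widths = as.integer(p$architecture$widths),
                         activations = p$architecture$activations,
                         learning_rate = p$architecture$learning_rate,
                         l2 = p$architecture$l2),
                    class = "eet_mlp_architecture")
  scalers <- NULL
  if (!is.null(p$scalers))
    scalers <- structure(list(
      feature_center = unlist(p$scalers$feature_center),
      feature_scale = unlist(p$scalers$feature_scale),
      target_scale = unlist(p$scalers$target_scale)), class = "eet_scalers")
  structure(list(W = lapply(p$W, as.matrix),
                 b = lapply(p$b, as.numeric),
                 arch = arch, seed = p$seed, scalers = scalers,
                 history = if (!is.null(p$history)) tibble::as_tibble(p$history)),
            class = "eet_mlp")
}
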