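# A tiny synthetic regression problem: targets are a smooth positive map of
# the features, so a small network should fit it well.
make_synthetic_db <- function(n, seed) {
  withr::with_seed(seed, {
    x <- matrix(runif(n * 3, -1, 1), n, 3)
  })
  db <- tibble::tibble(record_id = seq_len(n),
                       h_0 = x[, 1], h_1 = x[, 2], h_2 = x[, 3])
  db$transfer_time_ps <- 5 + 2 * x[, 1] - 1.5 * x[, 2] + x[, 3]
  db$efficiency <- 0.8 + 0.1 * x[, 2]
  db
}

test_that("initialization is deterministic and counts parameters correctly", {
  arch <- mlp_architecture(64, hidden = c(64, 128), activations = "rectifier")
  m1 <- init_mlp(arch, seed = 2)
  m2 <- init_mlp(arch, seed = 2)
  expect_equal(m1$W, m2$W)
  expect_equal(m1$b, m2$b)
  m3 <- init_mlp(arch, seed = 3)
  expect_false(identical(m1$W, m3$W))
  n_par <- sum(vapply(m1$W, length, 1)) + sum(vapply(m1$b, length, 1))
  widths <- c(64, 64, 128, 2)
  expect_equal(n_par, sum(widths[-4] * widths[-1]) + sum(widths[-1]))
  # the last two layers alone carry 64*128+128 + 128*2+2 = 8578 parameters
  expect_equal(length(m1$W[[2]]) + length(m1$b[[2]]) +
                 length(m1$W[[3]]) + length(m1$b[[3]]), 8578)
  expect_true(all(vapply(m1$b, function(b) all(b == 0), TRUE)))
})

test_that("all five activation functions are differentiable and consistent", {
  x <- seq(-3.1, 3.1, by = 0.27)  # grid avoids the rectifier kink at 0
  h <- 1e-6
  for (nm in c("rectifier", "tanh", "logistic", "softsign", "softplus")) {
    act <- mlp_activation(nm)
    fd <- (act$f(x + h) - act$f(x - h)) / (2 * h)
    expect_equal(act$df(x, act$f(x)), fd, tolerance = 1e-4, label = nm)
  }
  # softplus is stable for large inputs and strictly positive
  sp <- mlp_activation("softplus")
  expect_equal(sp$f(1000), 1000)
  expect_true(all(sp$f(c(-40, 0, 40)) > 0))
  expect_error(mlp_activation("swish"), "activation")
})

test_that("analytic gradients match finite differences", {
  set.seed(4)
  arch <- mlp_architecture(3, hidden = c(4), activations = "tanh", l2 = 0)
  model <- init_mlp(arch, seed = 4)
  x <- matrix(rnorm(6, sd = 0.5), 2, 3)
  y <- matrix(runif(4), 2, 2)
  g <- mlp_gradients(model, x, y)
  # the reported loss is the pure MSE term, so check against l2 = 0 first
  loss_at <- function(mod) mlp_gradients(mod, x, y)$loss
  h <- 1e-6
  for (l in seq_along(model$W)) {
    for (idx in c(1, length(model$W[[l]]))) {
      mp <- model; mp$W[[l]][idx] <- mp$W[[l]][idx] + h
      mm <- model; mm$W[[l]][idx] <- mm$W[[l]][idx] - h
      expect_equal(g$W[[l]][idx], (loss_at(mp) - loss_at(mm)) / (2 * h),
                   tolerance = 1e-5)
    }
    mp <- model; mp$b[[l]][1] <- mp$b[[l]][1] + h
    mm <- model; mm$b[[l]][1] <- mm$b[[l]][1] - h
    expect_equal(g$b[[l]][1], (loss_at(mp) - loss_at(mm)) / (2 * h),
                 tolerance = 1e-5)
  }
  # the L2 penalty adds 2*l2*W to hidden-layer gradients, output untouched
  model2 <- model
  model2$arch$l2 <- 1e-3
  g2 <- mlp_gradients(model2, x, y)
  expect_equal(g2$W[[1]], g$W[[1]] + 2e-3 * model$W[[1]], tolerance = 1e-10)
  expect_equal(g2$W[[2]], g$W[[2]], tolerance = 1e-12)
})

test_that("training recovers a smooth positive map to within 2 percent", {
  db <- make_synthetic_db(600, seed = 5)
  db <- split_dataset(db, n_valid = 100, n_test = 100, seed = 1)
  train <- db[db$split == "pool", ]
  valid <- db[db$split == "valid", ]
  test <- db[db$split == "test", ]
  sc <- fit_scalers(train)
  arch <- mlp_architecture(3, hidden = c(32, 32), activations = "tanh",
                           learning_rate = 3e-3, l2 = 1e-8)
  model <- train_mlp(init_mlp(arch, seed = 6), train, valid, sc,
                     training_config(batch_size = 50, max_epochs = 300,
                                     seed = 2))
  pred <- predict(model, test)
  err <- mean_relative_absolute_error(pred$transfer_time_ps,
                                      test$transfer_time_ps)
  expect_lt(err, 2)
  expect_true(all(pred$transfer_time_ps > 0))
  expect_true(all(pred$efficiency > 0))
})

test_that("early stopping restores the best-validation weights", {
  db <- make_synthetic_db(300, seed = 7)
  db <- split_dataset(db, n_valid = 60, n_test = 60, seed = 1)
  train <- db[db$split == "pool", ]
  valid <- db[db$split == "valid", ]
  sc <- fit_scalers(train)
  arch <- mlp_architecture(3, hidden = c(16), activations = "softsign",
                           learning_rate = 1e-2)
  model <- train_mlp(init_mlp(arch, seed = 8), train, valid, sc,
                     training_config(batch_size = 30, max_epochs = 120,
                                     patience = 3, seed = 3))
  h <- model$history
  best_epoch <- h$epoch[h$best]
  expect_length(best_epoch, 1)
  expect_equal(min(h$valid_error_pct), h$valid_error_pct[h$epoch == best_epoch])
  # the restored model reproduces the recorded best validation error
  pv <- predict(model, valid)
  expect_equal(mean_relative_absolute_error(pv$transfer_time_ps,
                                            valid$transfer_time_ps),
               min(h$valid_error_pct), tolerance = 1e-8)
  # stopping rule: the run either hit max_epochs or ended on 3 increases
  if (nrow(h) < 120) {
    tail4 <- utils::tail(h$valid_error_pct, 4)
    expect_true(all(diff(tail4) > 0))
  }
})

test_that("a divergent learning rate raises an informative error", {
  db <- make_synthetic_db(200, seed = 9)
  db <- split_dataset(db, 40, 40, seed = 1)
  train <- db[db$split == "pool", ]
  valid <- db[db$split == "valid", ]
  sc <- fit_scalers(train)
  arch <- mlp_architecture(3, hidden = c(16), activations = "rectifier",
                           learning_rate = 1e100)
  expect_error(train_mlp(init_mlp(arch, seed = 1), train, valid, sc,
                         training_config(batch_size = 20, max_epochs = 50,
                                         seed = 1)),
               "diverged")
})

test_that("models roundtrip through JSON with identical predictions", {
  db <- make_synthetic_db(150, seed = 10)
  db <- split_dataset(db, 30, 30, seed = 1)
  train <- db[db$split == "pool", ]
  valid <- db[db$split == "valid", ]
  sc <- fit_scalers(train)
  arch <- mlp_architecture(3, hidden = c(8, 8),
                           activations = c("tanh", "logistic"))
  model <- train_mlp(init_mlp(arch, seed = 11), train, valid, sc,
                     training_config(batch_size = 30, max_epochs = 5, seed = 2))
  p <- withr::local_tempfile(fileext = ".json")
  write_mlp(model, p)
  back <- read_mlp(p)
  expect_identical(predict(back, valid), predict(model, valid))
  expect_equal(back$history$valid_error_pct, model$history$valid_error_pct)
})

test_that("predict accepts a frenkel_hamiltonian and checks dimensions", {
  arch <- mlp_architecture(64, hidden = c(4))
  model <- init_mlp(arch, seed = 1)
  db <- build_database(dataset_ranges("FMO"), 4, engine = "redfield", seed = 2)
  model$scalers <- fit_scalers(db)
  h <- sample_hamiltonian(dataset_ranges("FMO"), seed = 3)
  out <- predict(model, h)
  expect_equal(nrow(out), 1)
  expect_true(out$transfer_time_ps > 0 && out$efficiency > 0)
  # batch predictions equal concatenated single-input predictions
  batch <- predict(model, db)
  singles <- do.call(rbind, lapply(1:4, function(i) predict(model, db[i, ])))
  expect_equal(batch, singles)
  h21 <- sample_hamiltonian(dataset_ranges("CP43"), seed = 3)
  expect_error(predict(model, h21), "64")
})
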