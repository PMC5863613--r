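test_that("build_database is deterministic and schema-complete", {
  db1 <- build_database(dataset_ranges("FMO"), 6, engine = "redfield", seed = 3)
  db2 <- build_database(dataset_ranges("FMO"), 6, engine = "redfield", seed = 3)
  expect_equal(as.data.frame(db1), as.data.frame(db2))
  expect_s3_class(db1, "eet_database")
  expect_equal(nrow(db1), 6)
  expect_true(all(c("seed", "engine", "split", "transfer_time_ps",
                    "efficiency") %in% names(db1)))
  expect_equal(sum(grepl("^h_[0-9]+$", names(db1))), 64)
  expect_true(all(db1$transfer_time_ps > 0))
  expect_true(all(db1$efficiency > 0 & db1$efficiency <= 1))
})

test_that("split_dataset partitions records disjointly and reproducibly", {
  db <- build_database(dataset_ranges("FMO"), 20, engine = "redfield", seed = 4)
  s1 <- split_dataset(db, n_valid = 5, n_test = 5, seed = 11)
  s2 <- split_dataset(db, n_valid = 5, n_test = 5, seed = 11)
  expect_equal(s1$split, s2$split)
  expect_equal(sort(unique(s1$split)), c("pool", "test", "valid"))
  expect_equal(as.vector(table(s1$split)[c("pool", "test", "valid")]),
               c(10L, 5L, 5L))
  s3 <- split_dataset(db, n_valid = 5, n_test = 5, seed = 12)
  expect_false(identical(s1$split, s3$split))
})

test_that("pca_select handles the degenerate extremes", {
  db <- build_database(dataset_ranges("FMO"), 12, engine = "redfield", seed = 5)
  expect_equal(sort(pca_select(db, 12)), 1:12)
  expect_length(pca_select(db, 1), 1)
  expect_error(pca_select(db, 0), "k")
  expect_error(pca_select(db, 13), "k")
})

test_that("pca_select is equivariant under record permutation", {
  db <- build_database(dataset_ranges("RC"), 15, engine = "redfield", seed = 6)
  sel <- pca_select(db, 7)
  perm <- c(15:8, 1:7)
  sel_p <- pca_select(db[perm, ], 7)
  expect_setequal(perm[sel_p], sel)
})

test_that("greedy farthest-point dispersion is at least half of brute force", {
  set.seed(99)
  z <- matrix(rnorm(40), 20, 2)
  db <- tibble::tibble(record_id = 1:20)
  feat <- as.data.frame(z)
  names(feat) <- c("h_0", "h_1")
  db <- dplyr::bind_cols(db, feat)
  db$transfer_time_ps <- 1
  db$efficiency <- 1
  for (k in c(3, 5)) {
    sel <- pca_select(db, k, variance_fraction = 1)
    zs <- scale(z)
    disp <- function(idx) min(dist(zs[idx, , drop = FALSE]))
    expect_gte(disp(sel), 0.5 * brute_force_dispersion(zs, k))
  }
})

test_that("scalers roundtrip features and targets to 1e-10", {
  db <- build_database(dataset_ranges("FMO"), 10, engine = "redfield", seed = 7)
  sc <- fit_scalers(db)
  xy <- apply_scalers(sc, feature_matrix(db),
                      as.matrix(db[, c("transfer_time_ps", "efficiency")]))
  expect_equal(colMeans(xy$features), rep(0, ncol(xy$features)),
               tolerance = 1e-10, ignore_attr = TRUE)
  back <- invert_scalers(sc, targets = xy$targets)$targets
  expect_equal(back[, 1], db$transfer_time_ps, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(back[, 2], db$efficiency, tolerance = 1e-10, ignore_attr = TRUE)
  xb <- invert_scalers(sc, features = xy$features)$features
  expect_equal(xb, feature_matrix(db), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("database files roundtrip through csv and jsonl", {
  db <- build_database(dataset_ranges("RC"), 5, engine = "redfield", seed = 8)
  db <- split_dataset(db, 1, 1, seed = 1)
  for (ext in c(".csv", ".jsonl")) {
    p <- withr::local_tempfile(fileext = ext)
    write_database(db, p)
    back <- read_database(p)
    expect_equal(feature_matrix(back), feature_matrix(db), tolerance = 1e-12)
    expect_equal(back$transfer_time_ps, db$transfer_time_ps, tolerance = 1e-12)
    expect_equal(back$split, db$split)
  }
})

test_that("read_database renames external column dialects", {
  db <- build_database(dataset_ranges("FMO"), 3, engine = "redfield", seed = 9)
  p <- withr::local_tempfile(fileext = ".csv")
  renamed <- db
  names(renamed)[names(renamed) == "transfer_time_ps"] <- "tau_ps"
  utils::write.csv(as.data.frame(renamed), p, row.names = FALSE)
  back <- read_database(p, mapping = c(transfer_time_ps = "tau_ps"))
  expect_equal(back$transfer_time_ps, db$transfer_time_ps, tolerance = 1e-12)
  expect_true(all(back$split == "pool"))
})
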