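#' Build a database of transfer properties for sampled Hamiltonians
#'
#' Draws `n` Hamiltonians from `ranges` with reproducible per-record seeds
#' (`seed + index`), labels each with the requested engine, and returns one
#' record per successful simulation. Records that fail (no transfer to the
#' acceptor, non-convergence, resource errors) are excluded; their seeds
#' and error messages are kept in the `failures` attribute and reported as
#' a warning, so the batch never aborts on a single bad draw.
#'
#' @param ranges A [sampling_ranges()] / [dataset_ranges()] object.
#' @param n Number of Hamiltonians to sample.
#' @param engine `"redfield"` (secular Redfield, fast) or `"heom"`
#'   (depth-converged HEOM via [converged_transfer_time()]).
#' @param bath A [bath_parameters()].
#' @param sink A [sink_parameters()].
#' @param seed Integer base seed.
#' @param ... Passed on to [converged_transfer_time()] when
#'   `engine = "heom"`.
#' @return A tibble with columns `h_0 ... h_{n_sites^2-1}` (row-major
#'   flattened Hamiltonian, cm^-1), `transfer_time_ps`, `efficiency`,
#'   `engine`, `seed` and `split` (initially all `"pool"`), of class
#'   `eet_database`. Failed records are listed in `attr(, "failures")`.
#' @export
build_database <- function(ranges, n, engine = c("redfield", "heom"),
                           bath = bath_parameters(), sink = sink_parameters(),
                           seed = 1, ...) {
  stopifnot(inherits(ranges, "sampling_ranges"), n >= 1)
  engine <- match.arg(engine)
  rows <- vector("list", n)
  fails <- list()
  for (i in seq_len(n)) {
    rec_seed <- seed + i
    h <- sample_hamiltonian(ranges, seed = rec_seed)
    res <- tryCatch({
      st <- if (engine == "redfield") {
        transfer_statistics(propagate_secular_redfield(h, bath, sink), sink)
      } else {
        converged_transfer_time(h, bath, sink, ...)$stats
      }
      tibble::tibble(!!!stats::setNames(as.list(flatten_hamiltonian(h)),
                                        paste0("h_", seq_len(h$n_sites^2) - 1)),
                     transfer_time_ps = st$transfer_time_ps,
                     efficiency = st$efficiency,
                     engine = engine, seed = rec_seed, split = "pool")
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1]] <-
        tibble::tibble(index = i, seed = rec_seed, message = conditionMessage(res))
    } else {
      rows[[i]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  failures <- dplyr::bind_rows(fails)
  if (nrow(failures) > 0)
    warning(sprintf("%d of %d records failed and were excluded (seeds: %s)",
                    nrow(failures), n, paste(failures$seed, collapse = ", ")),
            call. = FALSE)
  attr(out, "failures") <- failures
  class(out) <- c("eet_database", class(out))
  out
}

#' Assign train/validation/test splits
#'
#' Marks `n_valid` and `n_test` uniformly sampled, disjoint records as
#' `"valid"` and `"test"`; the remainder keeps (or regains) the `"pool"`
#' tag. Deterministic for a given seed.
#'
#' @param records An [build_database()] tibble (or any tibble with a
#'   `split` column).
#' @param n_valid,n_test Validation / test set sizes.
#' @param seed Integer seed.
#' @return The records with an updated `split` column.
#' @export
split_dataset <- function(records, n_valid, n_test, seed = 1) {
  n <- nrow(records)
  if (n_valid + n_test >= n)
    stop("n_valid + n_test must be smaller than the number of records",
         call. = FALSE)
  idx <- withr::with_seed(seed, sample.int(n, n_valid + n_test))
  records$split <- "pool"
  if (n_valid > 0) records$split[idx[seq_len(n_valid)]] <- "valid"
  if (n_test > 0) records$split[idx[n_valid + seq_len(n_test)]] <- "test"
  records
}

feature_matrix <- function(records) {
  cols <- grep("^h_[0-9]+$", names(records), value = TRUE)
  if (length(cols) == 0) stop("no feature columns h_0, h_1, ... found", call. = FALSE)
  cols <- cols[order(as.integer(sub("^h_", "", cols)))]
  as.matrix(records[, cols])
}

#' Select a maximally separated training subset in PCA space
#'
#' Standardizes the pool features (zero-variance dimensions are passed
#' through unscaled), projects onto the smallest set of leading principal
#' components explaining at least `variance_fraction` of the variance, and
#' greedily picks `k` points by farthest-point (max-min Euclidean)
#' selection, starting from the point farthest from the pool centroid.
#' Ties are broken by the lowest row index, so the result is deterministic
#' and permutation-equivariant.
#'
#' @param pool A feature matrix, or a records tibble with `h_*` columns.
#' @param k Number of points to select (1 <= k <= pool size).
#' @param variance_fraction Minimum explained variance for the retained
#'   components (default 0.95).
#' @return Integer vector of `k` selected row indices, in selection order.
#' @export
pca_select <- function(pool, k, variance_fraction = 0.95) {
  x <- if (is.matrix(pool)) pool else feature_matrix(pool)
  n <- nrow(x)
  if (k < 1 || k > n) stop("k must be between 1 and the pool size", call. = FALSE)
  sdev <- apply(x, 2, stats::sd)
  keep_scale <- ifelse(sdev > 0, sdev, 1)
  xs <- scale(x, center = TRUE, scale = keep_scale)
  p <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  ev <- p$sdev^2
  if (sum(ev) == 0) {
    z <- xs[, 1, drop = FALSE]           # all points identical
  } else {
    m <- which(cumsum(ev) / sum(ev) >= variance_fraction)[1]
    z <- p$x[, seq_len(max(m, 1)), drop = FALSE]
  }
  centroid <- colMeans(z)
  d2c <- rowSums((z - rep(centroid, each = n))^2)
  sel <- integer(k)
  sel[1] <- which.max(d2c)               # which.max takes the first (lowest) index
  mind <- rowSums((z - rep(z[sel[1], ], each = n))^2)
  if (k > 1) for (j in 2:k) {
    mind[sel[seq_len(j - 1)]] <- -Inf
    sel[j] <- which.max(mind)
    mind <- pmin(mind, rowSums((z - rep(z[sel[j], ], each = n))^2))
  }
  sel
}

#' Fit feature and target scalers on training records
#'
#' Features are standardized per dimension to mean 0 and variance 1
#' (zero-variance dimensions are centred but left unscaled); targets are
#' divided by their (positive) training means, which preserves positivity.
#'
#' @param records Training records ([build_database()] schema), >= 2 rows.
#' @return An `eet_scalers` object with `feature_center`, `feature_scale`
#'   and `target_scale` (named: `transfer_time_ps`, `efficiency`).
#' @export
fit_scalers <- function(records) {
  if (nrow(records) < 2) stop("need at least 2 training records", call. = FALSE)
  x <- feature_matrix(records)
  ctr <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  tgt <- c(transfer_time_ps = mean(records$transfer_time_ps),
           efficiency = mean(records$efficiency))
  if (any(tgt <= 0)) stop("target means must be positive", call. = FALSE)
  structure(list(feature_center = ctr,
                 feature_scale = ifelse(sdv > 0, sdv, 1),
                 target_scale = tgt),
            class = "eet_scalers")
}

#' Apply or invert fitted scalers
#'
#' @param scalers An [fit_scalers()] result.
#' @param features Feature matrix (rows = records) or `NULL`.
#' @param targets Two-column target matrix (`transfer_time_ps`,
#'   `efficiency`) or `NULL`.
#' @return A list with the transformed `features` and/or `targets`.
#' @export
apply_scalers <- function(scalers, features = NULL, targets = NULL) {
  stopifnot(inherits(scalers, "eet_scalers"))
  out <- list()
  if (!is.null(features)) {
    features <- as.matrix(features)
    out$features <- sweep(sweep(features, 2, scalers$feature_center), 2,
                          scalers$feature_scale, "/")
  }
  if (!is.null(targets))
    out$targets <- sweep(as.matrix(targets), 2, scalers$target_scale, "/")
  out
}

#' @rdname apply_scalers
#' @export
invert_scalers <- function(scalers, features = NULL, targets = NULL) {
  stopifnot(inherits(scalers, "eet_scalers"))
  out <- list()
  if (!is.null(features))
    out$features <- sweep(sweep(as.matrix(features), 2, scalers$feature_scale, "*"),
                          2, scalers$feature_center, "+")
  if (!is.null(targets))
    out$targets <- sweep(as.matrix(targets), 2, scalers$target_scale, "*")
  out
}

#' Read and write record databases
#'
#' CSV is the native format (`h_0 ...`, `transfer_time_ps`, `efficiency`,
#' `engine`, `seed`, `split`); files ending in `.jsonl` are written/read as
#' JSON lines. `mapping` renames foreign column layouts on read, e.g.
#' `c(transfer_time_ps = "t_mean")` to import a file whose transfer-time
#' column is called `t_mean`.
#'
#' @param records A records tibble.
#' @param path File path (`.csv` or `.jsonl`).
#' @param mapping Optional named character vector `c(ours = "theirs")`.
#' @return `read_database()` returns the records tibble; `write_database()`
#'   returns `path` invisibly.
#' @export
write_database <- function(records, path) {
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_len(nrow(records)))
      writeLines(jsonlite::toJSON(as.list(records[i, ]), auto_unbox = TRUE,
                                  digits = I(17)), con)
  } else {
    utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_database
#' @export
read_database <- function(path, mapping = NULL) {
  if (grepl("\\.jsonl$", path)) {
    rows <- lapply(readLines(path), function(l)
      tibble::as_tibble(jsonlite::fromJSON(l)))
    out <- dplyr::bind_rows(rows)
  } else {
    out <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  }
  if (!is.null(mapping)) {
    for (ours in names(mapping)) {
      theirs <- mapping[[ours]]
      if (!theirs %in% names(out))
        stop("mapped column not found: ", theirs, call. = FALSE)
      names(out)[names(out) == theirs] <- ours
    }
  }
  if (!"split" %in% names(out)) out$split <- "pool"
  class(out) <- c("eet_database", class(out))
  out
}
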