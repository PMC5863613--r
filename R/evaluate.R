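#' Mean relative absolute error of transfer-time predictions
#'
#' `100 * mean(|t_pred - t_ref| / t_ref)` in percent.
#'
#' @param predicted,reference Equal-length numeric vectors; all references
#'   must be strictly positive.
#' @return The error in percent (scalar >= 0).
#' @export
mean_relative_absolute_error <- function(predicted, reference) {
  if (length(predicted) != length(reference) || length(reference) < 1)
    stop("predicted and reference must have equal length >= 1", call. = FALSE)
  if (any(reference <= 0))
    stop("all reference values must be strictly positive", call. = FALSE)
  100 * mean(abs(predicted - reference) / reference)
}

#' Signed relative deviation of an approximate transfer time
#'
#' `(t_ref - t_approx) / t_ref`: positive when the approximation
#' underestimates the reference.
#'
#' @param t_ref Reference (exact) transfer times, strictly positive.
#' @param t_approx Approximate transfer times.
#' @return Vector of signed relative deviations.
#' @export
signed_relative_deviation <- function(t_ref, t_approx) {
  if (any(t_ref <= 0))
    stop("all reference values must be strictly positive", call. = FALSE)
  (t_ref - t_approx) / t_ref
}

#' Fraction of records where the network beats Redfield
#'
#' Share of records with `|network deviation| < |redfield deviation|`
#' (strict inequality; ties count as not-better).
#'
#' @param network_dev,redfield_dev Equal-length signed-deviation vectors.
#' @return Fraction in `[0, 1]`.
#' @export
quadrant_fraction <- function(network_dev, redfield_dev) {
  if (length(network_dev) != length(redfield_dev) || length(network_dev) < 1)
    stop("deviation vectors must have equal length >= 1", call. = FALSE)
  mean(abs(network_dev) < abs(redfield_dev))
}

histogram_summary <- function(x, breaks = 30) {
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  tibble::tibble(bin_left = utils::head(h$breaks, -1),
                 bin_right = utils::tail(h$breaks, -1),
                 count = h$counts)
}

#' Build an evaluation report over database splits
#'
#' For each predictor (a named list of transfer-time vectors aligned with
#' the records, e.g. `list(network = ..., redfield = ...)`) and each split,
#' computes the mean relative absolute error against the records'
#' reference `transfer_time_ps`, the per-record signed deviations, and —
#' when both a `network` and a `redfield` predictor are present — the
#' per-split fraction of records where the network is more accurate.
#' Histogram summaries of the reference times and of each predictor's
#' deviations are included for plotting.
#'
#' @param records A records tibble with `transfer_time_ps` and `split`.
#' @param predictions Named list of numeric vectors, each of length
#'   `nrow(records)`.
#' @return An `eet_report` with `errors` (split x predictor table),
#'   `deviations`, `quadrants`, `histograms` and `n_records`.
#' @export
make_report <- function(records, predictions) {
  if (!is.list(predictions) || is.null(names(predictions)) ||
      any(names(predictions) == ""))
    stop("predictions must be a named list of vectors", call. = FALSE)
  bad <- vapply(predictions, function(p) length(p) != nrow(records), TRUE)
  if (any(bad))
    stop("prediction lengths must match the record count (mismatch: ",
         paste(names(predictions)[bad], collapse = ", "), ")", call. = FALSE)
  ref <- records$transfer_time_ps
  splits <- unique(records$split)

  dev <- dplyr::bind_rows(lapply(names(predictions), function(nm)
    tibble::tibble(predictor = nm, record = seq_along(ref),
                   split = records$split,
                   deviation = signed_relative_deviation(ref, predictions[[nm]]))))
  errors <- dplyr::bind_rows(lapply(names(predictions), function(nm)
    dplyr::bind_rows(lapply(splits, function(s) {
      i <- records$split == s
      tibble::tibble(predictor = nm, split = s, n = sum(i),
                     delta_tau_pct = mean_relative_absolute_error(
                       predictions[[nm]][i], ref[i]))
    }))))
  quadrants <- NULL
  if (all(c("network", "redfield") %in% names(predictions))) {
    dn <- signed_relative_deviation(ref, predictions$network)
    dr <- signed_relative_deviation(ref, predictions$redfield)
    quadrants <- dplyr::bind_rows(lapply(splits, function(s) {
      i <- records$split == s
      tibble::tibble(split = s, n = sum(i),
                     network_better = quadrant_fraction(dn[i], dr[i]))
    }))
  }
  hists <- c(list(reference_transfer_time = histogram_summary(ref)),
             stats::setNames(lapply(names(predictions), function(nm)
               histogram_summary(dev$deviation[dev$predictor == nm])),
               paste0("deviation_", names(predictions))))
  structure(list(errors = errors, deviations = dev, quadrants = quadrants,
                 histograms = hists, n_records = nrow(records)),
            class = "eet_report")
}

#' @export
print.eet_report <- function(x, ...) {
  cat(sprintf("<eet_report> %d records\n", x$n_records))
  cat("  Mean relative absolute error of transfer times (%):\n")
  wide <- tidyr::pivot_wider(x$errors[, c("predictor", "split", "delta_tau_pct")],
                             names_from = "split", values_from = "delta_tau_pct")
  w <- as.data.frame(wide)
  num <- vapply(w, is.numeric, TRUE)
  w[num] <- lapply(w[num], function(v) sprintf("%.2f", v))
  print(w, row.names = FALSE)
  if (!is.null(x$quadrants)) {
    cat("  Fraction of records where the network beats Redfield:\n")
    q <- as.data.frame(x$quadrants)
    q$network_better <- sprintf("%.3f", q$network_better)
    print(q, row.names = FALSE)
  }
  invisible(x)
}

#' Write or re-read an evaluation report
#'
#' JSON round trip: `read_report(write_report(r, path))` reproduces the
#' report exactly.
#'
#' @param report An [make_report()] result.
#' @param path `.json` output path.
#' @return `read_report()` returns the `eet_report`; `write_report()`
#'   returns `path` invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eet_report"))
  writeLines(jsonlite::toJSON(unclass(report), digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  p <- jsonlite::fromJSON(path)
  structure(list(errors = tibble::as_tibble(p$errors),
                 deviations = tibble::as_tibble(p$deviations),
                 quadrants = if (!is.null(p$quadrants)) tibble::as_tibble(p$quadrants),
                 histograms = lapply(p$histograms, tibble::as_tibble),
                 n_records = p$n_records),
            class = "eet_report")
}

#' Tidy an evaluation report
#'
#' @param x An `eet_report`.
#' @param ... Unused.
#' @return The per-split, per-predictor error table as a tibble.
#' @export
tidy.eet_report <- function(x, ...) x$errors

#' One-row summary of an evaluation report
#'
#' @param x An `eet_report`.
#' @param ... Unused.
#' @return A one-row tibble: record count, the overall error per predictor
#'   and (when available) the overall network-beats-Redfield fraction.
#' @export
glance.eet_report <- function(x, ...) {
  overall <- x$errors |>
    dplyr::group_by(.data$predictor) |>
    dplyr::summarise(err = sum(.data$delta_tau_pct * .data$n) / sum(.data$n))
  out <- tibble::as_tibble(stats::setNames(as.list(overall$err),
                                           paste0("delta_tau_", overall$predictor)))
  out$n_records <- x$n_records
  if (!is.null(x$quadrants))
    out$network_better <- sum(x$quadrants$network_better * x$quadrants$n) /
      sum(x$quadrants$n)
  out
}

#' Plot the deviation histograms of an evaluation report
#'
#' @param object An `eet_report`.
#' @param ... Unused.
#' @return A ggplot of signed-deviation histograms, one facet per
#'   predictor.
#' @export
autoplot.eet_report <- function(object, ...) {
  ggplot2::ggplot(object$deviations,
                  ggplot2::aes(x = .data$deviation)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~predictor) +
    ggplot2::labs(x = "signed relative deviation (t_ref - t_pred) / t_ref",
                  y = "records")
}
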