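#' Frenkel exciton Hamiltonian
#'
#' Constructs a Frenkel exciton Hamiltonian: site excitation energies
#' `energies` (cm^-1) on the diagonal and electronic inter-site couplings
#' `couplings` (cm^-1) off the diagonal. The coupling matrix must be
#' symmetric with an all-zero diagonal. Site indices are 1-based, matching
#' the conventional pigment numbering of the light-harvesting literature.
#'
#' @param energies Numeric vector of site excitation energies in cm^-1
#'   (length >= 2).
#' @param couplings Symmetric numeric matrix of couplings in cm^-1 with
#'   zero diagonal, dimension `length(energies)` squared.
#' @param label Free-text label for the system.
#' @return An object of class `frenkel_hamiltonian` with elements
#'   `n_sites`, `energies`, `couplings`, `label`.
#' @examples
#' h <- frenkel_hamiltonian(c(12000, 12100), matrix(c(0, 50, 50, 0), 2))
#' as.matrix(h)
#' @export
frenkel_hamiltonian <- function(energies, couplings, label = "") {
  energies <- as.numeric(energies)
  n <- length(energies)
  if (n < 2) stop("a Frenkel Hamiltonian needs at least 2 sites", call. = FALSE)
  couplings <- as.matrix(couplings)
  if (!is.numeric(couplings) || any(!is.finite(couplings)) || any(!is.finite(energies)))
    stop("energies and couplings must be finite numerics", call. = FALSE)
  if (!all(dim(couplings) == c(n, n)))
    stop("couplings must be an n_sites x n_sites matrix", call. = FALSE)
  if (max(abs(couplings - t(couplings))) > 0)
    stop("couplings must be exactly symmetric", call. = FALSE)
  if (any(diag(couplings) != 0))
    stop("couplings must have a zero diagonal", call. = FALSE)
  structure(
    list(n_sites = n, energies = energies, couplings = unname(couplings),
         label = as.character(label)),
    class = "frenkel_hamiltonian"
  )
}

#' @export
as.matrix.frenkel_hamiltonian <- function(x, ...) {
  m <- x$couplings
  diag(m) <- x$energies
  m
}

#' @export
print.frenkel_hamiltonian <- function(x, ...) {
  cat(sprintf("<frenkel_hamiltonian> %d sites%s\n", x$n_sites,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat("site energies (cm^-1):", paste(format(x$energies, digits = 6), collapse = " "), "\n")
  vmax <- max(abs(x$couplings))
  cat(sprintf("couplings (cm^-1): |V| <= %.4g\n", vmax))
  invisible(x)
}

#' Build a Hamiltonian from a full matrix
#'
#' @param m Real symmetric matrix in cm^-1; diagonal entries are the site
#'   energies, off-diagonals the couplings.
#' @param label Free-text label.
#' @return A [frenkel_hamiltonian()].
#' @export
hamiltonian_from_matrix <- function(m, label = "") {
  m <- as.matrix(m)
  if (max(abs(m - t(m))) > 1e-9 * max(1, max(abs(m))))
    stop("matrix must be symmetric", call. = FALSE)
  m <- (m + t(m)) / 2
  v <- m
  diag(v) <- 0
  frenkel_hamiltonian(diag(m), v, label = label)
}

#' Uniform sampling ranges for random Hamiltonians
#'
#' Site energies are drawn from `Uniform(eps_low, eps_high)` and couplings
#' from `Uniform(-v_abs, +v_abs)`, independently for every element.
#'
#' @param n_sites Number of pigments.
#' @param eps_low,eps_high Bounds of the site-energy range in cm^-1.
#' @param v_abs Half-width of the symmetric coupling range in cm^-1.
#' @param label Free-text label.
#' @return A `sampling_ranges` object.
#' @export
sampling_ranges <- function(n_sites, eps_low, eps_high, v_abs, label = "") {
  if (n_sites < 2) stop("n_sites must be >= 2", call. = FALSE)
  if (eps_low > eps_high) stop("eps_low must be <= eps_high", call. = FALSE)
  if (v_abs < 0) stop("v_abs must be >= 0", call. = FALSE)
  structure(list(n_sites = as.integer(n_sites), eps_low = eps_low,
                 eps_high = eps_high, v_abs = v_abs, label = label),
            class = "sampling_ranges")
}

#' Sampling ranges of the four standard datasets
#'
#' Parameter neighbourhoods of four pigment-protein complexes: the
#' Fenna-Matthews-Olson complex (FMO), the photosystem II reaction-center
#' core (RC), and the RC extended by the CP43 or CP47 antenna complex.
#'
#' @param label One of `"FMO"`, `"RC"`, `"CP43"`, `"CP47"`.
#' @return A [sampling_ranges()] object.
#' @export
dataset_ranges <- function(label = c("FMO", "RC", "CP43", "CP47")) {
  label <- match.arg(label)
  switch(label,
    RC   = sampling_ranges(8,  14800, 15000, 50,  "RC"),
    FMO  = sampling_ranges(8,  12000, 12800, 100, "FMO"),
    CP43 = sampling_ranges(21, 14800, 15100, 60,  "CP43"),
    CP47 = sampling_ranges(24, 14500, 15300, 100, "CP47")
  )
}

#' Sample a random Frenkel Hamiltonian
#'
#' Draws each site energy and each independent coupling (upper triangle,
#' mirrored) uniformly within `ranges`. Deterministic for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param ranges A [sampling_ranges()] object.
#' @param seed Integer seed.
#' @return A [frenkel_hamiltonian()].
#' @export
sample_hamiltonian <- function(ranges, seed) {
  stopifnot(inherits(ranges, "sampling_ranges"))
  n <- ranges$n_sites
  withr::with_seed(seed, {
    eps <- stats::runif(n, ranges$eps_low, ranges$eps_high)
    v <- matrix(0, n, n)
    iu <- upper.tri(v)
    v[iu] <- stats::runif(sum(iu), -ranges$v_abs, ranges$v_abs)
    v <- v + t(v)
  })
  frenkel_hamiltonian(eps, v, label = sprintf("%s seed=%d", ranges$label, seed))
}

#' Flatten a Hamiltonian into a feature vector
#'
#' Row-major concatenation of the full n x n matrix (length n^2), the input
#' representation used by the surrogate models.
#'
#' @param h A [frenkel_hamiltonian()].
#' @return Numeric vector of length `n_sites^2`.
#' @seealso [unflatten_hamiltonian()]
#' @export
flatten_hamiltonian <- function(h) {
  stopifnot(inherits(h, "frenkel_hamiltonian"))
  as.vector(t(as.matrix(h)))
}

#' Rebuild a Hamiltonian from a flattened feature vector
#'
#' @param x Numeric vector of length n^2 (row-major).
#' @param label Free-text label.
#' @return A [frenkel_hamiltonian()].
#' @export
unflatten_hamiltonian <- function(x, label = "") {
  n <- round(sqrt(length(x)))
  if (n * n != length(x)) stop("feature length is not a perfect square", call. = FALSE)
  hamiltonian_from_matrix(t(matrix(x, n, n)), label = label)
}

#' Permute the sites of a Hamiltonian
#'
#' Relabels pigments: `H'[i, j] = H[perm[i], perm[j]]`. Eigenvalues are
#' invariant, and transfer statistics are invariant when the donor and
#' acceptor indices are co-permuted.
#'
#' @param h A [frenkel_hamiltonian()].
#' @param perm Integer permutation of `1:n_sites`.
#' @return The permuted [frenkel_hamiltonian()].
#' @export
permute_sites <- function(h, perm) {
  stopifnot(inherits(h, "frenkel_hamiltonian"))
  perm <- as.integer(perm)
  if (length(perm) != h$n_sites || !setequal(perm, seq_len(h$n_sites)))
    stop("perm must be a permutation of 1:n_sites", call. = FALSE)
  m <- as.matrix(h)[perm, perm, drop = FALSE]
  hamiltonian_from_matrix(m, label = h$label)
}

#' Read / write Hamiltonians
#'
#' Two plain-text dialects are supported: a JSON object with fields
#' `n_sites`, `energies_cm1`, `couplings_cm1` and `label`, and a
#' whitespace-delimited full n x n matrix (diagonal = site energies), the
#' layout in which literature Hamiltonians are usually printed.
#'
#' @param path File path. Files ending in `.json` use the JSON dialect.
#' @return `read_hamiltonian()` returns a [frenkel_hamiltonian()];
#'   `write_hamiltonian()` returns `path` invisibly.
#' @export
read_hamiltonian <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    frenkel_hamiltonian(x$energies_cm1, matrix(unlist(x$couplings_cm1), x$n_sites, x$n_sites),
                        label = if (is.null(x$label)) "" else x$label)
  } else {
    m <- as.matrix(utils::read.table(path, header = FALSE, comment.char = "#"))
    hamiltonian_from_matrix(unname(m), label = basename(path))
  }
}

#' @rdname read_hamiltonian
#' @param h A [frenkel_hamiltonian()] to write.
#' @export
write_hamiltonian <- function(h, path) {
  stopifnot(inherits(h, "frenkel_hamiltonian"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(n_sites = h$n_sites, energies_cm1 = h$energies,
           couplings_cm1 = h$couplings, label = h$label),
      path, auto_unbox = TRUE, digits = I(17))
  } else {
    utils::write.table(format(as.matrix(h), digits = 12, trim = TRUE), path,
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
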