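#' Resample a time series onto a uniform dyadic grid
#'
#' Linear interpolation of `(times, values)` at `n` uniformly spaced points
#' spanning `[times[1], times[T]]`. Needed because measured time courses
#' (e.g. 36 or 17 points) are rarely a power of 2 in length.
#'
#' @param times strictly increasing numeric vector.
#' @param values numeric vector, same length as `times`.
#' @param n number of output samples (>= 2).
#' @return numeric vector of length `n`.
#' @export
resample_series <- function(times, values, n) {
  if (length(times) != length(values)) stop("times and values differ in length")
  if (length(times) < 2L) stop("need at least 2 points to resample")
  if (n < 2L) stop("n must be >= 2")
  grid <- seq(times[1L], times[length(times)], length.out = n)
  stats::approx(times, values, xout = grid)$y
}

is_pow2 <- function(n) n >= 1L && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L

#' Orthonormal Haar matrix
#'
#' The n x n orthonormal Haar transform matrix, built recursively:
#' `H_1 = [1]`, `H_2n = rbind(H_n (x) (1,1), I_n (x) (1,-1)) / sqrt(2)`.
#' Rows are orthonormal, so the transform preserves the Euclidean norm.
#'
#' @param n a power of 2.
#' @return n x n numeric matrix.
#' @export
haar_matrix <- function(n) {
  if (!is_pow2(n)) stop("n must be a power of 2, got ", n)
  H <- matrix(1, 1L, 1L)
  while (nrow(H) < n) {
    m <- nrow(H)
    H <- rbind(kronecker(H, matrix(c(1, 1), 1L)),
               kronecker(diag(m), matrix(c(1, -1), 1L))) / sqrt(2)
  }
  H
}

#' Haar discrete wavelet transform
#'
#' Multiplies the signal by the orthonormal Haar matrix. By orthonormality,
#' `sum(coeffs^2) == sum(signal^2)` (Parseval) and [haar_idwt()] inverts it
#' exactly.
#'
#' @param signal numeric vector whose length is a power of 2.
#' @return coefficient vector, same length.
#' @export
haar_dwt <- function(signal) {
  n <- length(signal)
  if (!is_pow2(n)) stop("signal length must be a power of 2, got ", n)
  drop(haar_matrix(n) %*% signal)
}

#' Inverse Haar transform
#' @param coeffs coefficient vector, length a power of 2.
#' @return reconstructed signal.
#' @export
haar_idwt <- function(coeffs) {
  n <- length(coeffs)
  if (!is_pow2(n)) stop("coefficient length must be a power of 2, got ", n)
  drop(crossprod(haar_matrix(n), coeffs))
}

#' Encode an expression dataset as Haar wavelet features
#'
#' Each gene's profile is linearly resampled onto an `n`-point uniform grid
#' over its time span and transformed with the orthonormal Haar basis. The
#' default `n = 64` is the standard encoding width; results with `n = 32` are
#' very close for smooth profiles.
#'
#' @param dataset an [expression_dataset()].
#' @param n number of wavelet coefficients (power of 2, default 64).
#' @param center_genes subtract each gene's mean resampled value before the
#'   transform (default off: downstream cosine similarity is scale-invariant).
#' @return Object of class `feature_matrix`: `gene_ids`, `coeffs` (G x n),
#'   `n`, `basis = "haar"`.
#' @export
encode <- function(dataset, n = 64L, center_genes = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!is_pow2(n)) stop("n must be a power of 2, got ", n)
  H <- haar_matrix(n)
  ts <- dataset$time_stamps
  grid <- seq(ts[1L], ts[length(ts)], length.out = n)
  # resample all genes at once: approx per gene on a shared grid
  res <- t(apply(dataset$values, 1L, function(v) stats::approx(ts, v, xout = grid)$y))
  if (center_genes) res <- res - rowMeans(res)
  coeffs <- res %*% t(H)
  rownames(coeffs) <- dataset$gene_ids
  structure(list(gene_ids = dataset$gene_ids, coeffs = coeffs,
                 n = as.integer(n), basis = "haar"),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d genes x %d %s coefficients\n",
              nrow(x$coeffs), x$n, x$basis))
  invisible(x)
}
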