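#' Normalize a similarity graph into a row-stochastic matrix
#'
#' Produces the transition matrix N of a Markov chain whose states are genes.
#' Three normalizations are available:
#' \describe{
#'   \item{markov}{`N = D^-1 W` (D = diagonal of row sums).}
#'   \item{symmetric}{`D^-1/2 W D^-1/2`, then rows rescaled to sum to 1.}
#'   \item{sinkhorn}{alternating row/column scaling until both row and column
#'     sums are 1 within 1e-8 (doubly stochastic), at most 10000 sweeps.}
#' }
#' Every returned matrix has rows summing to 1 within 1e-10.
#'
#' @param graph a (usually sparsified) `similarity_graph`.
#' @param method one of `"markov"`, `"symmetric"`, `"sinkhorn"`.
#' @return row-stochastic numeric matrix N with gene dimnames.
#' @export
normalize_stochastic <- function(graph, method = c("markov", "symmetric", "sinkhorn")) {
  method <- match.arg(method)
  W <- if (inherits(graph, "similarity_graph")) graph$W else as.matrix(graph)
  rs <- rowSums(W)
  zero <- which(rs <= 0)
  if (length(zero))
    stop("isolated gene(s) with zero similarity row: ",
         paste(rownames(W)[zero], collapse = ", "))
  N <- switch(method,
    markov = W / rs,
    symmetric = {
      S <- W / sqrt(rs) / rep(sqrt(rs), each = nrow(W))
      S / rowSums(S)
    },
    sinkhorn = {
      A <- W
      ok <- FALSE
      for (it in seq_len(10000L)) {
        A <- A / rowSums(A)
        A <- t(t(A) / colSums(A))
        res <- max(abs(rowSums(A) - 1), abs(colSums(A) - 1))
        if (res < 1e-8) { ok <- TRUE; break }
      }
      if (!ok) stop("sinkhorn scaling did not converge; residual = ",
                    format(res, digits = 3))
      A / rowSums(A)   # exact row-stochasticity after the final column pass
    })
  attr(N, "normalization") <- method
  N
}

#' Diffusion-map embedding from a row-stochastic matrix
#'
#' Solves the eigenvalue problem for N, sorts eigenpairs by descending real
#' eigenvalue, discards the trivial constant eigenvector (eigenvalue 1), and
#' returns coordinates `coords[, j] = lambda_(j+1) * v_(j+1)` (diffusion-map
#' scaling), j = 1..d. Eigenvector signs are fixed by making the
#' largest-magnitude entry positive. If the graph is disconnected (eigenvalue
#' 1 with multiplicity > 1) a warning is issued; complex eigenvalues are
#' truncated to their real parts with a warning.
#'
#' @param N row-stochastic matrix (genes x genes).
#' @param d embedding dimension (default 3), must be `< G`.
#' @return Object of class `manifold_embedding`: `gene_ids`, `eigenvalues`
#'   (length d+1, including the trivial leading 1), `coords` (G x d),
#'   `local_dim` (NULL until [local_dimension()] fills it), `normalization`.
#' @export
eigen_embed <- function(N, d = 3L) {
  N <- as.matrix(N)
  G <- nrow(N)
  if (d >= G) stop("d must be smaller than the number of genes")
  if (d < 1L) stop("d must be positive")
  e <- eigen(N)
  lam <- e$values; V <- e$vectors
  if (is.complex(lam)) {
    if (max(abs(Im(lam))) > 1e-8)
      warning("complex eigenvalues encountered; using real parts")
    lam <- Re(lam); V <- Re(V)
  }
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]; V <- V[, ord, drop = FALSE]
  if (sum(lam > 1 - 1e-8) > 1L)
    warning("eigenvalue 1 has multiplicity > 1: graph appears disconnected")
  coords <- matrix(0, G, d)
  for (j in seq_len(d)) {
    v <- V[, j + 1L]
    v <- v * sign(v[which.max(abs(v))])
    coords[, j] <- lam[j + 1L] * v
  }
  ids <- rownames(N)
  if (is.null(ids)) ids <- paste0("g", seq_len(G))
  rownames(coords) <- ids
  colnames(coords) <- paste0("dim", seq_len(d))
  structure(list(gene_ids = ids, eigenvalues = lam[seq_len(d + 1L)],
                 coords = coords, local_dim = NULL,
                 normalization = attr(N, "normalization") %||% "unknown"),
            class = "manifold_embedding")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.manifold_embedding <- function(x, ...) {
  cat(sprintf("manifold_embedding: %d genes in %d dims (%s normalization)\n",
              nrow(x$coords), ncol(x$coords), x$normalization))
  cat("eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' Per-gene local dimension score
#'
#' For each gene, takes the gene plus its `k_nb` nearest neighbours in the
#' manifold coordinates, runs PCA on the neighbourhood's rows in feature
#' space, and returns the (linearly interpolated) number of principal axes
#' needed to reach a cumulative variance fraction `tau`. A gene lying on a
#' clean 1-D structure scores about 1; isotropic noise in D dimensions scores
#' near D. Scores are measured in feature space, so they can exceed the
#' embedding dimension.
#'
#' Because the neighbourhood sample size is comparable to (or smaller than)
#' the feature dimension, raw sample eigenvalues over-disperse and the
#' threshold count is biased low. The neighbourhood covariance is therefore
#' estimated with Schäfer–Strimmer-style shrinkage: off-diagonal entries are
#' damped by a data-driven intensity equal to the ratio of their estimated
#' sampling variance to their magnitude. Genuine correlation structure is
#' left intact (intensity near 0) while pure-noise neighbourhoods are pulled
#' towards their diagonal (intensity near 1), restoring the flat spectrum.
#'
#' @param features `feature_matrix` or numeric matrix (rows = genes) in which
#'   PCA is run.
#' @param coords G x d matrix of manifold coordinates defining neighbourhoods.
#' @param k_nb neighbourhood size (default 30); must satisfy
#'   `d + 1 <= k_nb < G`.
#' @param tau cumulative variance fraction threshold (default 0.95).
#' @return numeric vector of length G; a degenerate neighbourhood with zero
#'   total variance scores 0 with a warning.
#' @export
local_dimension <- function(features, coords, k_nb = 30L, tau = 0.95) {
  X <- if (inherits(features, "feature_matrix")) features$coeffs else as.matrix(features)
  coords <- as.matrix(coords)
  G <- nrow(coords)
  if (nrow(X) != G) stop("features and coords disagree on gene count")
  if (k_nb >= G) stop("k_nb must be smaller than the number of genes")
  if (k_nb < ncol(coords) + 1L) stop("k_nb must be at least d + 1")
  sq <- rowSums(coords^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(coords), 0)
  D <- ncol(X)
  out <- numeric(G)
  degenerate <- FALSE
  for (g in seq_len(G)) {
    nb <- order(D2[g, ])[seq_len(k_nb + 1L)]   # gene itself + k_nb nearest
    Y <- X[nb, , drop = FALSE]
    n_nb <- nrow(Y)
    Y <- Y - rep(colMeans(Y), each = n_nb)
    S <- crossprod(Y) / n_nb
    if (sum(diag(S)) <= 0) { out[g] <- 0; degenerate <- TRUE; next }
    # shrink off-diagonal covariances by their estimated noise fraction
    off <- row(S) != col(S)
    s2_off <- sum(S[off]^2)
    if (s2_off > 0) {
      V <- (crossprod(Y^2) / n_nb - S^2) / n_nb   # Var-hat of each entry
      rho <- min(1, max(0, sum(V[off]) / s2_off))
      S[off] <- (1 - rho) * S[off]
    }
    lam <- pmax(eigen(S, symmetric = TRUE, only.values = TRUE)$values, 0)
    cf <- cumsum(lam) / sum(lam)
    m <- which(cf >= tau)[1L]
    prev <- if (m == 1L) 0 else cf[m - 1L]
    out[g] <- (m - 1L) + (tau - prev) / (cf[m] - prev)
  }
  if (degenerate) warning("degenerate neighbourhood(s) with zero variance: score 0")
  names(out) <- rownames(coords)
  out
}
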