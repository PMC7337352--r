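#' Cosine similarity mapped to the unit interval \[0, 1\]
#'
#' Returns `(1 + cos(theta)) / 2` where `theta` is the angle between `u` and
#' `v`: 1 means the angle is zero (maximal similarity), 0 means the vectors
#' are anti-parallel, orthogonal vectors score 0.5.
#'
#' @param u,v nonzero numeric vectors of equal length.
#' @return similarity in the unit interval \[0, 1\].
#' @export
cosine01 <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero vector has undefined direction")
  s <- (1 + sum(u * v) / (nu * nv)) / 2
  min(max(s, 0), 1)
}

#' Build the dense gene-by-gene similarity matrix
#'
#' `W[i, j]` is the [cosine01()] similarity of the two genes' feature rows
#' (default), or the heat-kernel similarity `exp(-||u - v||^2 / (2 sigma^2))`.
#' Either way W is symmetric with unit diagonal and entries in the unit interval \[0, 1\].
#'
#' @param features a `feature_matrix` (or a plain numeric matrix, rows =
#'   genes).
#' @param method `"cosine"` (default) or `"heat"`.
#' @param sigma bandwidth for the heat kernel; default is the median pairwise
#'   feature distance.
#' @return Object of class `similarity_graph`: `gene_ids`, `W`, `mask`
#'   (NULL until sparsified), `k` (NA until sparsified), `method`.
#' @export
build_W <- function(features, method = c("cosine", "heat"), sigma = NULL) {
  method <- match.arg(method)
  X <- if (inherits(features, "feature_matrix")) features$coeffs else as.matrix(features)
  gene_ids <- if (inherits(features, "feature_matrix")) features$gene_ids else rownames(X)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(X)))
  norms <- sqrt(rowSums(X^2))
  if (method == "cosine") {
    zero <- which(norms == 0)
    if (length(zero))
      stop("all-zero feature row(s): ", paste(gene_ids[zero], collapse = ", "))
    C <- tcrossprod(X / norms)
    W <- (1 + C) / 2
  } else {
    sq <- rowSums(X^2)
    D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(X), 0)
    if (is.null(sigma)) {
      d <- sqrt(D2[upper.tri(D2)])
      sigma <- stats::median(d)
      if (sigma == 0) stop("median pairwise distance is zero; supply sigma")
    }
    W <- exp(-D2 / (2 * sigma^2))
  }
  W[W > 1] <- 1; W[W < 0] <- 0
  W <- (W + t(W)) / 2
  diag(W) <- 1
  dimnames(W) <- list(gene_ids, gene_ids)
  structure(list(gene_ids = gene_ids, W = W, mask = NULL, k = NA_integer_,
                 method = method),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph: %d genes, %s%s\n", nrow(x$W), x$method,
              if (is.na(x$k)) " (dense)" else sprintf(", k-symmetric NN k=%d", x$k)))
  invisible(x)
}

#' Sparsify a similarity graph by k-symmetric nearest neighbours
#'
#' For each gene the k largest off-diagonal similarities are selected; the
#' kept mask is the logical-or of this selection with its transpose, so the
#' result is symmetric and every gene keeps at least k neighbours. Kept
#' entries retain their similarity, all others are set to zero (the unit
#' diagonal is retained). Ties at the k-th similarity are broken by lower
#' gene index.
#'
#' @param graph a dense `similarity_graph`.
#' @param k neighbour count (default 10), must be `< G`.
#' @return A sparsified `similarity_graph` with `mask` and `k` set.
#' @export
sparsify_symmetric_knn <- function(graph, k = 10L) {
  stopifnot(inherits(graph, "similarity_graph"))
  W <- graph$W
  G <- nrow(W)
  if (k >= G) stop("k must be smaller than the number of genes (k=", k, ", G=", G, ")")
  if (k < 1L) stop("k must be positive")
  mask <- matrix(FALSE, G, G)
  for (i in seq_len(G)) {
    w <- W[i, ]
    w[i] <- -Inf                       # diagonal excluded from selection
    ord <- order(-w, seq_len(G))       # ties -> lower index
    mask[i, ord[seq_len(k)]] <- TRUE
  }
  mask <- mask | t(mask)
  Ws <- W * mask
  diag(Ws) <- 1
  diag(mask) <- FALSE
  dimnames(Ws) <- dimnames(W)
  structure(list(gene_ids = graph$gene_ids, W = Ws, mask = mask,
                 k = as.integer(k), method = graph$method),
            class = "similarity_graph")
}
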