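#' k-means++ center initialization
#'
#' Arthur–Vassilvitskii seeding: the first center is uniform over the points;
#' each subsequent center is sampled with probability proportional to the
#' squared Euclidean distance to the nearest center chosen so far (so points
#' coinciding with a chosen center have weight 0).
#'
#' @param points numeric matrix (rows = points).
#' @param K number of centers; must not exceed the number of distinct points.
#' @param seed optional integer seed (consumes the global RNG stream if NULL).
#' @return K x d matrix of centers (rows of `points`).
#' @export
kmeanspp_init <- function(points, K, seed = NULL) {
  points <- as.matrix(points)
  if (!is.null(seed)) set.seed(seed)
  n_distinct <- nrow(unique(points))
  if (K > n_distinct)
    stop("K exceeds the number of distinct points (", n_distinct, ")")
  n <- nrow(points)
  idx <- integer(K)
  idx[1L] <- sample.int(n, 1L)
  if (K > 1L) {
    d2 <- rowSums((points - rep(points[idx[1L], ], each = n))^2)
    for (j in 2L:K) {
      if (all(d2 == 0)) stop("fewer than K distinct points remain")
      idx[j] <- sample.int(n, 1L, prob = d2)
      d2j <- rowSums((points - rep(points[idx[j], ], each = n))^2)
      d2 <- pmin(d2, d2j)
    }
  }
  points[idx, , drop = FALSE]
}

# G x K matrix of divergences from every point to every center
bregman_div_matrix <- function(points, centers, divergence) {
  if (divergence == "squared_euclidean") {
    sqp <- rowSums(points^2); sqc <- rowSums(centers^2)
    pmax(outer(sqp, sqc, "+") - 2 * tcrossprod(points, centers), 0)
  } else { # generalized KL: sum x log(x/c) - x + c
    xlx <- rowSums(points * log(points)) - rowSums(points)
    xlc <- tcrossprod(points, log(centers))
    sc <- rowSums(centers)
    pmax(matrix(xlx, nrow(points), nrow(centers)) - xlc +
           rep(sc, each = nrow(points)), 0)
  }
}

#' Bregman k-means clustering
#'
#' Lloyd-style batch clustering under a Bregman divergence (squared Euclidean
#' or generalized Kullback–Leibler). For any Bregman divergence the centroid
#' minimizing total divergence is the arithmetic mean, so the update step is
#' shared. Iterations stop when labels no longer change or after `max_iter`
#' sweeps; the per-iteration potential is non-increasing. The best of
#' `restarts` independent k-means++-seeded runs (by final potential) is
#' returned.
#'
#' @param points numeric matrix (rows = points, e.g. manifold coordinates).
#' @param K number of clusters.
#' @param divergence `"squared_euclidean"` (default) or `"kl"`. KL requires
#'   strictly positive coordinates; otherwise a minimum shift
#'   `x - min(x) + 1e-6` is applied (with a message).
#' @param restarts number of independent runs (default 1).
#' @param max_iter Lloyd iteration cap per run (default 300).
#' @param seed optional integer seed; all restarts draw from the one stream.
#' @return Object of class `clustering_result`: `labels` (1..K, named by
#'   rownames), `K`, `potential`, `centers`, `potential_trace` (best run),
#'   `restart_potentials`, `method`, `params`, `seed`.
#' @export
bregman_kmeans <- function(points, K, divergence = c("squared_euclidean", "kl"),
                           restarts = 1L, max_iter = 300L, seed = NULL) {
  divergence <- match.arg(divergence)
  points <- as.matrix(points)
  if (!is.null(seed)) set.seed(seed)
  if (divergence == "kl" && min(points) <= 0) {
    message("KL divergence with non-positive coordinates: applying min-shift")
    points <- points - min(points) + 1e-6
  }
  best <- NULL
  restart_potentials <- numeric(restarts)
  for (r in seq_len(restarts)) {
    run <- lloyd_once(points, K, divergence, max_iter)
    restart_potentials[r] <- run$potential
    if (is.null(best) || run$potential < best$potential) best <- run
  }
  labels <- best$labels
  names(labels) <- rownames(points)
  structure(list(labels = labels, K = as.integer(K),
                 potential = best$potential, centers = best$centers,
                 potential_trace = best$trace,
                 restart_potentials = restart_potentials,
                 method = "bregman_kmeans",
                 params = list(divergence = divergence, restarts = restarts,
                               max_iter = max_iter),
                 seed = seed),
            class = "clustering_result")
}

lloyd_once <- function(points, K, divergence, max_iter) {
  centers <- kmeanspp_init(points, K)
  labels <- integer(nrow(points))
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    D <- bregman_div_matrix(points, centers, divergence)
    new_labels <- max.col(-D, ties.method = "first")
    # empty cluster: re-seed at the point farthest from its center
    for (kk in seq_len(K)) {
      if (!any(new_labels == kk)) {
        far <- which.max(D[cbind(seq_len(nrow(D)), new_labels)])
        message("empty cluster ", kk, " re-seeded at farthest point")
        centers[kk, ] <- points[far, ]
        D[, kk] <- bregman_div_matrix(points, centers[kk, , drop = FALSE],
                                      divergence)
        new_labels <- max.col(-D, ties.method = "first")
      }
    }
    trace <- c(trace, sum(D[cbind(seq_len(nrow(D)), new_labels)]))
    if (it > 1L && all(new_labels == labels)) { labels <- new_labels; break }
    labels <- new_labels
    for (kk in seq_len(K)) {
      members <- labels == kk
      if (any(members))
        centers[kk, ] <- colMeans(points[members, , drop = FALSE])
    }
  }
  D <- bregman_div_matrix(points, centers, divergence)
  potential <- sum(D[cbind(seq_len(nrow(D)), labels)])
  list(labels = labels, centers = centers, potential = potential, trace = trace)
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result (%s): K=%d, sizes %s", x$method, x$K,
              paste(tabulate(x$labels, x$K), collapse = "/")))
  if (!is.null(x$potential) && is.finite(x$potential))
    cat(sprintf(", potential %.6g", x$potential))
  cat("\n")
  invisible(x)
}

#' Model-selection curve over a range of K
#'
#' Runs [bregman_kmeans()] for every K in `k_range` with `restarts`
#' independent runs each, recording the mean and standard deviation of the
#' run potentials and keeping the best run per K. The elbow is the K
#' maximizing the ratio of the mean-potential drop into K over the drop out
#' of K — a sharp decrease before, mild decrease after.
#'
#' @param points numeric matrix.
#' @param k_range integer vector of K values (default 3:15).
#' @param restarts runs per K (default 5).
#' @param divergence passed to [bregman_kmeans()].
#' @param seed optional integer seed.
#' @return Object of class `selection_curve`: `k`, `mean_potential`,
#'   `sd_potential`, `best` (list of `clustering_result` per K), `elbow_k`.
#' @export
selection_curve <- function(points, k_range = 3:15, restarts = 5L,
                            divergence = "squared_euclidean", seed = NULL) {
  points <- as.matrix(points)
  if (min(k_range) < 2L || max(k_range) >= nrow(points))
    stop("k_range must lie within [2, G)")
  if (!is.null(seed)) set.seed(seed)
  k_range <- sort(unique(as.integer(k_range)))
  means <- sds <- numeric(length(k_range))
  best <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    res <- bregman_kmeans(points, k_range[i], divergence = divergence,
                          restarts = restarts)
    means[i] <- mean(res$restart_potentials)
    sds[i] <- stats::sd(res$restart_potentials)
    if (restarts == 1L) sds[i] <- 0
    best[[i]] <- res
  }
  elbow_k <- NA_integer_
  if (length(k_range) >= 3L) {
    drops <- pmax(-diff(means), 0)               # drop into k_range[i+1]
    # floor the outgoing drop at a fraction of the total decline so the
    # ratio cannot blow up on the flat tail of the curve
    floor_ <- max(1e-3 * (max(means) - min(means)), 1e-300)
    ratio <- drops[-length(drops)] / pmax(drops[-1L], floor_)
    elbow_k <- k_range[which.max(ratio) + 1L]
  }
  structure(list(k = k_range, mean_potential = means, sd_potential = sds,
                 best = best, elbow_k = elbow_k, restarts = restarts),
            class = "selection_curve")
}

#' @export
print.selection_curve <- function(x, ...) {
  cat("selection_curve over K =", paste(range(x$k), collapse = ".."),
      "| elbow at K =", x$elbow_k, "\n")
  invisible(x)
}

#' Non-negative matrix factorization clustering
#'
#' Factorizes a nonnegative matrix `X ~ F H` (F: G x K loadings, H: K x M
#' basis) by Lee–Seung multiplicative updates for the Frobenius objective,
#' which is non-increasing at every update. Gene g is assigned to the factor
#' with its largest loading `F[g, ]` (ties to the lower index).
#'
#' @param X nonnegative numeric matrix (e.g. the sparsified similarity
#'   matrix, which is nonnegative by construction).
#' @param K number of factors.
#' @param iters maximum update sweeps (default 500).
#' @param tol stop when the relative objective change falls below this
#'   (default 1e-10).
#' @param init `"nndsvd"` (default) seeds the factors from the positive and
#'   negative parts of the leading singular vectors, with zeros replaced by
#'   the matrix mean (deterministic, avoids zero-locking); `"random"` uses
#'   seeded uniform draws.
#' @param seed optional integer seed for the random initialization.
#' @return `clustering_result` with extra fields `F`, `H` and
#'   `objective_trace`.
#' @export
nnmf_cluster <- function(X, K, iters = 500L, tol = 1e-10,
                         init = c("nndsvd", "random"), seed = NULL) {
  init <- match.arg(init)
  X <- as.matrix(X)
  if (min(X) < 0) stop("NNMF requires a nonnegative input matrix")
  if (!is.null(seed)) set.seed(seed)
  G <- nrow(X); M <- ncol(X)
  if (init == "nndsvd") {
    fh <- nndsvd_init(X, K)
    F_ <- fh$F; H <- fh$H
  } else {
    sc <- sqrt(mean(X) / K)
    F_ <- matrix(stats::runif(G * K, 0.5, 1.5) * sc, G, K)
    H <- matrix(stats::runif(K * M, 0.5, 1.5) * sc, K, M)
  }
  eps <- 1e-12
  obj <- function() sum((X - F_ %*% H)^2)
  trace <- obj()
  for (it in seq_len(iters)) {
    H <- H * (crossprod(F_, X) / (crossprod(F_) %*% H + eps))
    F_ <- F_ * (X %*% t(H) / (F_ %*% tcrossprod(H) + eps))
    trace <- c(trace, obj())
    n <- length(trace)
    if (abs(trace[n - 1L] - trace[n]) <= tol * max(trace[1L], 1)) break
  }
  labels <- max.col(F_, ties.method = "first")
  names(labels) <- rownames(X)
  structure(list(labels = labels, K = as.integer(K), potential = trace[length(trace)],
                 centers = NULL, F = F_, H = H, objective_trace = trace,
                 method = "nnmf",
                 params = list(iters = iters, tol = tol), seed = seed),
            class = "clustering_result")
}

# Boutsidis-Gallopoulos NNDSVD seeding, dense variant: each factor pair is
# built from the dominant sign-consistent part of a leading singular triplet;
# zeros are replaced by the matrix mean so multiplicative updates cannot lock.
nndsvd_init <- function(X, K) {
  G <- nrow(X); M <- ncol(X)
  sv <- svd(X, nu = K, nv = K)
  F_ <- matrix(0, G, K); H <- matrix(0, K, M)
  F_[, 1L] <- sqrt(sv$d[1L]) * abs(sv$u[, 1L])
  H[1L, ] <- sqrt(sv$d[1L]) * abs(sv$v[, 1L])
  if (K > 1L) for (j in 2:K) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    n_p <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    n_n <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (n_p >= n_n && n_p > 0) {
      F_[, j] <- sqrt(sv$d[j] * n_p) * up / sqrt(sum(up^2))
      H[j, ] <- sqrt(sv$d[j] * n_p) * vp / sqrt(sum(vp^2))
    } else if (n_n > 0) {
      F_[, j] <- sqrt(sv$d[j] * n_n) * un / sqrt(sum(un^2))
      H[j, ] <- sqrt(sv$d[j] * n_n) * vn / sqrt(sum(vn^2))
    }
  }
  mn <- mean(X)
  F_[F_ <= 0] <- mn
  H[H <= 0] <- mn
  list(F = F_, H = H)
}

#' Affinity propagation clustering
#'
#' Frey–Dueck exemplar-based clustering by damped responsibility/availability
#' message passing on a similarity matrix. Exemplars are the points i with
#' `r(i,i) + a(i,i) > 0`; convergence is declared when the exemplar set is
#' stable for `conv_iter` consecutive sweeps. Every point is labeled by its
#' most similar exemplar (exemplars label themselves).
#'
#' @param S square similarity matrix (larger = more similar).
#' @param preference self-similarity (diagonal) controlling the number of
#'   clusters; `"median"` (default) uses the median off-diagonal similarity.
#' @param damping message damping factor in [0.5, 1).
#' @param max_iter maximum sweeps (default 500).
#' @param conv_iter sweeps of stable exemplars required (default 50).
#' @return `clustering_result` with extra field `exemplars` (indices).
#' @export
affinity_propagation <- function(S, preference = "median", damping = 0.9,
                                 max_iter = 500L, conv_iter = 50L) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n != ncol(S)) stop("S must be square")
  if (damping < 0.5 || damping >= 1) stop("damping must be in [0.5, 1)")
  if (n == 1L) {
    labels <- c(1L); names(labels) <- rownames(S)
    return(structure(list(labels = labels, K = 1L, potential = NA_real_,
                          exemplars = 1L, method = "affinity_propagation",
                          params = list(preference = preference, damping = damping),
                          seed = NULL),
                     class = "clustering_result"))
  }
  if (identical(preference, "median"))
    preference <- stats::median(S[row(S) != col(S)])
  diag(S) <- preference
  # tiny deterministic tie-break noise, scaled well below similarity spread
  spread <- max(S) - min(S)
  if (spread == 0) spread <- 1
  tb <- outer(seq_len(n), seq_len(n), function(i, j) sin(i * 12.9898 + j * 78.233))
  S <- S + 1e-10 * spread * tb
  R <- A <- matrix(0, n, n)
  stable <- 0L
  exemplars_prev <- integer(0)
  for (it in seq_len(max_iter)) {
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1L, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS; AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1L, max)
    Rmax <- matrix(max1, n, n)
    Rmax[cbind(seq_len(n), which1)] <- max2
    R <- damping * R + (1 - damping) * (S - Rmax)
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dAnew <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dAnew
    A <- damping * A + (1 - damping) * Anew
    exemplars <- which(diag(R) + diag(A) > 0)
    if (length(exemplars) && identical(exemplars, exemplars_prev)) {
      stable <- stable + 1L
      if (stable >= conv_iter) break
    } else stable <- 0L
    exemplars_prev <- exemplars
  }
  exemplars <- which(diag(R) + diag(A) > 0)
  if (length(exemplars) == 0L)
    stop("no exemplars identified after ", max_iter,
         " iterations; try a higher preference")
  labels <- max.col(S[, exemplars, drop = FALSE], ties.method = "first")
  labels[exemplars] <- seq_along(exemplars)
  names(labels) <- rownames(S)
  structure(list(labels = labels, K = length(exemplars), potential = NA_real_,
                 exemplars = exemplars, method = "affinity_propagation",
                 params = list(preference = preference, damping = damping,
                               max_iter = max_iter, conv_iter = conv_iter),
                 seed = NULL),
            class = "clustering_result")
}
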