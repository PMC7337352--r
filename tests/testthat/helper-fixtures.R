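# shared generators and independent oracles

# isotropic Gaussian blobs with known labels
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- as.matrix(centers)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      rep(centers[k, ], each = n_per)))
  rownames(pts) <- paste0("p", seq_len(nrow(pts)))
  list(points = pts, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# brute-force double-loop cosine01 similarity matrix
brute_cosine_W <- function(X) {
  G <- nrow(X)
  W <- matrix(NA_real_, G, G)
  for (i in seq_len(G)) for (j in seq_len(G))
    W[i, j] <- (1 + sum(X[i, ] * X[j, ]) /
                  (sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2)))) / 2
  W
}

# exhaustive k-largest-per-row union mask (digraph OR its reverse)
brute_knn_mask <- function(W, k) {
  G <- nrow(W)
  asym <- matrix(FALSE, G, G)
  for (i in seq_len(G)) {
    w <- W[i, ]
    w[i] <- -Inf
    ord <- order(-w, seq_len(G))
    asym[i, ord[seq_len(k)]] <- TRUE
  }
  asym | t(asym)
}

# eigen oracle for the markov normalization via the symmetric conjugate:
# N = D^-1 W is similar to M = D^-1/2 W D^-1/2 (symmetric); eigenvectors of
# N are D^-1/2 times those of M. A different solver path from eigen(N).
eigen_oracle_markov <- function(W, d) {
  rs <- rowSums(W)
  M <- W / sqrt(rs) / rep(sqrt(rs), each = nrow(W))
  e <- eigen(M, symmetric = TRUE)
  lam <- e$values
  coords <- matrix(0, nrow(W), d)
  for (j in seq_len(d)) {
    v <- e$vectors[, j + 1L] / sqrt(rs)
    v <- v / sqrt(sum(v^2))
    v <- v * sign(v[which.max(abs(v))])
    coords[, j] <- lam[j + 1L] * v
  }
  list(values = lam, coords = coords)
}

# brute-force empty-circumsphere verification of a tetrahedralization
delaunay_is_valid <- function(coords, tets, tol = 1e-7) {
  for (t in seq_len(nrow(tets))) {
    P <- coords[tets[t, ], , drop = FALSE]
    A <- 2 * (P[2:4, ] - rep(P[1L, ], each = 3L))
    b <- rowSums(P[2:4, ]^2) - sum(P[1L, ]^2)
    ctr <- solve(A, b)
    r2 <- sum((P[1L, ] - ctr)^2)
    others <- setdiff(seq_len(nrow(coords)), tets[t, ])
    d2 <- rowSums((coords[others, , drop = FALSE] -
                     rep(ctr, each = length(others)))^2)
    if (any(d2 < r2 * (1 - tol))) return(FALSE)
  }
  TRUE
}

# small expression fixture written by hand
write_tiny_expression <- function(path, delim = "\t") {
  lines <- c(paste(c("gene_id", "0", "10", "20", "30"), collapse = delim),
             paste(c("gA", "1", "2", "3", "4"), collapse = delim),
             paste(c("gB", "2", "2", "2", "2"), collapse = delim),
             paste(c("gC", "4", "3", "2", "1"), collapse = delim))
  writeLines(lines, path)
  path
}

# smaller synthetic design for fast end-to-end tests
tiny_spec <- function(seed = 1, noise_sd = 0.2)
  synthetic_spec(n_groups = 3L, genes_per_group = 20L, n_aperiodic = 40L,
                 n_time = 24L, n_cycles = 3L, total_minutes = 300,
                 noise_sd = noise_sd, n_sentinels = 5L, seed = seed)
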