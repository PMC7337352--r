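random_graph <- function(G, seed) {
  set.seed(seed)
  X <- matrix(rnorm(G * 8), G)
  build_W(X)
}

test_that("all three normalizations return row-stochastic matrices", {
  g <- sparsify_symmetric_knn(random_graph(15, 1), 4)
  for (m in c("markov", "symmetric", "sinkhorn")) {
    N <- normalize_stochastic(g, m)
    expect_equal(unname(rowSums(N)), rep(1, 15), tolerance = 1e-10)
    expect_true(all(N >= 0))
  }
})

test_that("markov normalization of an equal-row-sum W is doubly stochastic", {
  W <- matrix(0.2, 5, 5)
  diag(W) <- 1
  g <- structure(list(gene_ids = paste0("g", 1:5), W = W, mask = NULL,
                      k = NA_integer_, method = "cosine"),
                 class = "similarity_graph")
  N <- normalize_stochastic(g, "markov")
  r <- 1 + 4 * 0.2
  expect_equal(N, W / r, ignore_attr = TRUE)
  expect_equal(unname(colSums(N)), rep(1, 5), tolerance = 1e-12)
})

test_that("sinkhorn scaling balances rows and columns of a random matrix", {
  set.seed(9)
  W <- matrix(runif(100, 0.1, 1), 10)
  W <- (W + t(W)) / 2
  N <- normalize_stochastic(W, "sinkhorn")
  expect_equal(unname(rowSums(N)), rep(1, 10), tolerance = 1e-8)
  expect_equal(unname(colSums(N)), rep(1, 10), tolerance = 1e-8)
})

test_that("an isolated gene is reported by name", {
  W <- diag(0, 4)
  W[1, 2] <- W[2, 1] <- 0.5
  W[3, 4] <- W[4, 3] <- 0  # genes 3 and 4 isolated
  W[1, 1] <- W[2, 2] <- 1
  rownames(W) <- colnames(W) <- paste0("g", 1:4)
  expect_error(normalize_stochastic(W, "markov"), "g3")
})

test_that("the spectrum of N is bounded by 1 with a unit leading eigenvalue", {
  g <- sparsify_symmetric_knn(random_graph(20, 2), 5)
  N <- normalize_stochastic(g, "markov")
  emb <- eigen_embed(N, d = 3)
  expect_equal(emb$eigenvalues[1L], 1, tolerance = 1e-8)
  expect_true(all(abs(emb$eigenvalues) <= 1 + 1e-8))
})

test_that("a reducible two-block chain exposes its components", {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 0.8
  W[4:6, 4:6] <- 0.6
  diag(W) <- 1
  expect_warning(emb <- eigen_embed(normalize_stochastic(W, "markov"), d = 2),
                 "disconnected")
  expect_equal(sum(emb$eigenvalues > 1 - 1e-8), 2L)
  # first coordinate splits the blocks cleanly at its midpoint
  x <- emb$coords[, 1L]
  mid <- (max(x) + min(x)) / 2
  expect_true(all(x[1:3] > mid) && all(x[4:6] < mid) ||
                all(x[1:3] < mid) && all(x[4:6] > mid))
})

test_that("duplicated genes receive identical coordinates", {
  set.seed(3)
  X <- matrix(rnorm(8 * 6), 8)
  X[5, ] <- X[2, ]
  N <- normalize_stochastic(build_W(X), "markov")
  emb <- eigen_embed(N, d = 3)
  expect_equal(emb$coords[5, ], emb$coords[2, ], tolerance = 1e-8)
  expect_error(eigen_embed(N, d = 8), "smaller")
})

test_that("eigen-embedding matches the symmetric-conjugate oracle", {
  for (seed in 1:10) {
    g <- random_graph(8, seed + 100)       # dense: always connected
    N <- normalize_stochastic(g, "markov")
    emb <- eigen_embed(N, d = 3)
    orc <- eigen_oracle_markov(g$W, 3)
    expect_equal(emb$eigenvalues, orc$values[1:4], tolerance = 1e-8)
    expect_equal(emb$coords, orc$coords, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("embedding is invariant (up to axis sign) to gene reordering", {
  g <- random_graph(12, 77)
  N <- normalize_stochastic(g, "markov")
  emb <- eigen_embed(N, 3)
  perm <- sample(12)
  W2 <- g$W[perm, perm]
  emb2 <- eigen_embed(normalize_stochastic(W2, "markov"), 3)
  for (j in 1:3) {
    a <- emb$coords[perm, j]; b <- emb2$coords[, j]
    expect_true(isTRUE(all.equal(a, b, tolerance = 1e-7)) ||
                  isTRUE(all.equal(a, -b, tolerance = 1e-7)))
  }
})

test_that("local dimension recovers known intrinsic dimensions", {
  set.seed(13)
  # 200 points on a 1-D line embedded in 10-D
  dir <- rnorm(10); dir <- dir / sqrt(sum(dir^2))
  line <- outer(seq(0, 1, length.out = 200), dir)
  ld_line <- local_dimension(line, line, k_nb = 30)
  expect_lt(abs(mean(ld_line) - 1), 0.1)

  # isotropic 10-D Gaussian cloud approaches the ambient dimension
  cloud <- matrix(rnorm(500 * 10), 500)
  ld_cloud <- local_dimension(cloud, cloud, k_nb = 60)
  expect_lt(abs(mean(ld_cloud) - 10), 1)
})

test_that("degenerate identical neighbourhoods score zero dimension", {
  X <- matrix(1, 12, 5)
  co <- matrix(1, 12, 2)
  expect_warning(ld <- local_dimension(X, co, k_nb = 5), "degenerate")
  expect_equal(ld, rep(0, 12), ignore_attr = TRUE)
})

test_that("isotropic noise never lowers the mean local dimension of a plane", {
  set.seed(17)
  base <- cbind(matrix(rnorm(150 * 2), 150), matrix(0, 150, 8))
  noise <- matrix(rnorm(150 * 10), 150)
  means <- vapply(c(0, 0.05, 0.3), function(s) {
    X <- base + s * noise
    mean(local_dimension(X, X[, 1:3], k_nb = 30))
  }, numeric(1))
  expect_true(all(diff(means) >= -1e-8))
  expect_lt(abs(means[1] - 2), 0.2)   # clean plane scores about 2
})
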