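test_that("k-means++ seeds all distinct points when K equals their number", {
  pts <- rbind(c(0, 0), c(0, 0), c(1, 0), c(0, 1))
  got <- kmeanspp_init(pts, 3, seed = 4)
  expect_equal(nrow(unique(got)), 3L)
  expect_true(all(apply(got, 1, function(r)
    any(apply(pts, 1, function(p) all(p == r))))))
  expect_error(kmeanspp_init(pts, 4), "distinct")

  one <- kmeanspp_init(pts, 1, seed = 1)
  expect_equal(dim(one), c(1L, 2L))
})

test_that("k-means++ seeds well-separated blobs in nearly every run", {
  blobs <- make_blobs(20, rbind(c(0, 0), c(100, 0)), sd = 0.5, seed = 8)
  both <- 0L
  for (s in 1:200) {
    ctr <- kmeanspp_init(blobs$points, 2, seed = s)
    if (length(unique(ctr[, 1] > 50)) == 2L) both <- both + 1L
  }
  expect_gte(both / 200, 0.95)
})

test_that("Lloyd iterations monotonically decrease the potential", {
  set.seed(19)
  pts <- matrix(rnorm(120 * 3), 120)
  for (s in 1:50) {
    res <- bregman_kmeans(pts, 5, seed = s)
    expect_true(all(diff(res$potential_trace) <= 1e-9))
  }
})

test_that("potential vanishes when K equals the number of distinct points", {
  set.seed(23)
  pts <- matrix(rnorm(6 * 2), 6)
  res <- bregman_kmeans(pts, 6, seed = 1)
  expect_equal(res$potential, 0)
  expect_equal(sort(unique(res$labels)), 1:6)
})

test_that("planted Gaussian blobs are recovered exactly", {
  blobs <- make_blobs(100, 10 * rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      sd = 1, seed = 5)
  res <- bregman_kmeans(blobs$points, 3, restarts = 5, seed = 2)
  expect_equal(mclust::adjustedRandIndex(res$labels, blobs$labels), 1)
  # invariants of the result object
  expect_true(all(tabulate(res$labels, 3) > 0))
  D <- rowSums((blobs$points - res$centers[res$labels, ])^2)
  expect_equal(res$potential, sum(D), tolerance = 1e-9)
})

test_that("best-of-restarts is at least as good as any of its runs", {
  set.seed(29)
  pts <- matrix(rnorm(80 * 2), 80)
  res <- bregman_kmeans(pts, 6, restarts = 8, seed = 3)
  expect_equal(res$potential, min(res$restart_potentials))
  expect_length(res$restart_potentials, 8L)
})

test_that("clustering is invariant to point order", {
  blobs <- make_blobs(40, 10 * rbind(c(0, 0), c(1, 1)), sd = 0.5, seed = 6)
  res1 <- bregman_kmeans(blobs$points, 2, restarts = 3, seed = 11)
  perm <- sample(nrow(blobs$points))
  res2 <- bregman_kmeans(blobs$points[perm, ], 2, restarts = 3, seed = 11)
  expect_equal(mclust::adjustedRandIndex(res1$labels[perm], res2$labels), 1)
})

test_that("KL divergence clustering works after the positivity shift", {
  blobs <- make_blobs(30, rbind(c(5, 5), c(25, 25)), sd = 0.5, seed = 7)
  res <- bregman_kmeans(blobs$points, 2, divergence = "kl",
                        restarts = 3, seed = 1)
  expect_equal(mclust::adjustedRandIndex(res$labels, blobs$labels), 1)
})

test_that("the elbow of the selection curve finds the planted K", {
  blobs <- make_blobs(50, 10 * rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
                      sd = 0.7, seed = 9)
  sel <- selection_curve(blobs$points, k_range = 2:8, restarts = 5, seed = 13)
  expect_equal(sel$elbow_k, 4L)
  expect_true(all(sel$sd_potential >= 0))
  expect_length(sel$mean_potential, 7L)
  # mean potential decreases over K on planted data with enough restarts
  sel10 <- selection_curve(blobs$points, k_range = 2:8, restarts = 10, seed = 14)
  expect_true(all(diff(sel10$mean_potential) <= 1e-8))
})

test_that("restarts that converge to one labeling give zero spread", {
  blobs <- make_blobs(30, 100 * rbind(c(0, 0), c(1, 1)), sd = 0.1, seed = 10)
  sel <- selection_curve(blobs$points, k_range = 2:4, restarts = 5, seed = 15)
  expect_equal(sel$sd_potential[1L], 0, tolerance = 1e-12)
})

test_that("NNMF reconstructs an exactly factorable nonnegative matrix", {
  set.seed(33)
  F0 <- matrix(0, 30, 3)
  F0[1:10, 1] <- runif(10, 1, 2)
  F0[11:20, 2] <- runif(10, 1, 2)
  F0[21:30, 3] <- runif(10, 1, 2)
  H0 <- matrix(runif(3 * 12, 0.5, 1.5) *
                 rbind(c(rep(1, 4), rep(0, 8)),
                       c(rep(0, 4), rep(1, 4), rep(0, 4)),
                       c(rep(0, 8), rep(1, 4))), 3, 12)
  X <- F0 %*% H0
  res <- nnmf_cluster(X, 3, iters = 2000, tol = 0, seed = 21)
  expect_lte(res$potential, 1e-6)
  truth <- rep(1:3, each = 10)
  expect_equal(mclust::adjustedRandIndex(res$labels, truth), 1)
  expect_error(nnmf_cluster(-X, 3), "nonnegative")
})

test_that("NNMF multiplicative updates never increase the objective", {
  set.seed(35)
  X <- matrix(runif(40 * 15), 40)
  res <- nnmf_cluster(X, 4, iters = 500, tol = 0, seed = 22)
  expect_true(all(diff(res$objective_trace) <= 1e-9))
})

test_that("NNMF with a single factor yields one cluster", {
  set.seed(36)
  X <- matrix(runif(20 * 6), 20)
  res <- nnmf_cluster(X, 1, seed = 1)
  expect_equal(unname(unique(res$labels)), 1L)
})

test_that("affinity propagation handles degenerate inputs", {
  one <- matrix(0, 1, 1)
  res <- affinity_propagation(one)
  expect_equal(res$K, 1L)
  expect_equal(res$exemplars, 1L)

  # two identical points with preference far below their mutual similarity
  S <- matrix(c(0, 10, 10, 0), 2)
  res2 <- affinity_propagation(S, preference = -100, damping = 0.5)
  expect_equal(res2$K, 1L)
})

test_that("affinity propagation recovers three planted blobs exactly", {
  blobs <- make_blobs(20, 10 * rbind(c(0, 0), c(1, 0), c(0, 1)),
                      sd = 0.5, seed = 12)
  S <- -as.matrix(dist(blobs$points))^2
  res <- affinity_propagation(S, preference = "median", damping = 0.9)
  expect_equal(res$K, 3L)
  expect_equal(mclust::adjustedRandIndex(res$labels, blobs$labels), 1)
  # every point is labeled by the cluster of its exemplar
  expect_equal(unname(res$labels[res$exemplars]), seq_along(res$exemplars))
})

test_that("affinity propagation is invariant to a constant similarity shift", {
  blobs <- make_blobs(15, 10 * rbind(c(0, 0), c(1, 1)), sd = 0.5, seed = 14)
  S <- -as.matrix(dist(blobs$points))^2
  pref <- stats::median(S[row(S) != col(S)])
  r1 <- affinity_propagation(S, preference = pref, damping = 0.8)
  r2 <- affinity_propagation(S + 7, preference = pref + 7, damping = 0.8)
  expect_equal(mclust::adjustedRandIndex(r1$labels, r2$labels), 1)
})
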