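test_that("a single tetrahedron triangulates to the complete graph", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  e <- delaunay_edges(coords)
  expect_equal(nrow(e), 6L)
  expect_true(all(e[, 1] < e[, 2]))
  expect_equal(nrow(attr(e, "tetrahedra")), 1L)
})

test_that("random point sets satisfy the empty-circumsphere property", {
  for (seed in 1:5) {
    set.seed(seed)
    coords <- matrix(runif(20 * 3), 20)
    e <- delaunay_edges(coords)
    tets <- attr(e, "tetrahedra")
    expect_true(delaunay_is_valid(coords, tets))
    expect_equal(anyDuplicated(e), 0L)
  }
})

test_that("degenerate inputs follow the configured policy", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  expect_error(delaunay_edges(coords, degenerate = "error"), "general position")
  expect_message(e <- delaunay_edges(coords, degenerate = "jitter"), "jitter")
  expect_gt(nrow(e), 0L)

  coplanar <- cbind(matrix(runif(12 * 2), 12), 0)
  expect_error(suppressMessages(delaunay_edges(coplanar, degenerate = "jitter")),
               "degenerate|coplanar")
})

test_that("the edge set is invariant to rigid motions of the coordinates", {
  set.seed(44)
  coords <- matrix(rnorm(30 * 3), 30)
  e1 <- delaunay_edges(coords)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  e2 <- delaunay_edges(coords %*% Rz + 5)
  expect_equal(unclass(e1)[, ], unclass(e2)[, ], ignore_attr = TRUE)
})

test_that("edge correlations and p-values match the t-test oracle", {
  sim <- generate_synthetic(tiny_spec(seed = 2))
  ds <- sim$dataset
  set.seed(2)
  coords <- matrix(rnorm(length(ds$gene_ids) * 3), ncol = 3)
  e <- delaunay_edges(coords)
  tri <- score_edges(e, ds, coords)
  expect_true(all(abs(tri$edges$r) <= 1))
  expect_true(all(tri$edges$p > 0 & tri$edges$p <= 1))
  # independent oracle: cor.test on a sample of edges
  for (row in sample(nrow(tri$edges), 20)) {
    i <- match(tri$edges$gene_i[row], ds$gene_ids)
    j <- match(tri$edges$gene_j[row], ds$gene_ids)
    ct <- cor.test(ds$values[i, ], ds$values[j, ])
    expect_equal(tri$edges$p[row], ct$p.value, tolerance = 1e-6)
    expect_equal(tri$edges$r[row], unname(ct$estimate), tolerance = 1e-9)
  }
})

test_that("perfectly correlated and anti-correlated profiles get signed edges", {
  prof <- sin(seq(0, 4 * pi, length.out = 12))
  ds <- expression_dataset(c("up1", "up2", "down", "flatish"),
                          seq(0, 110, by = 10),
                          rbind(prof, 2 * prof, -prof,
                                prof + c(rep(0.5, 6), rep(-0.5, 6))))
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tri <- score_edges(delaunay_edges(coords), ds, coords)
  up <- tri$edges[tri$edges$gene_i == "up1" & tri$edges$gene_j == "up2", ]
  expect_equal(up$r, 1)
  expect_equal(up$sign, "positive")
  dn <- tri$edges[tri$edges$gene_i == "up1" & tri$edges$gene_j == "down", ]
  expect_equal(dn$r, -1)
  expect_equal(dn$sign, "negative")
})

test_that("zero-variance profiles drop their edges with a warning", {
  ds <- expression_dataset(c("a", "b", "c", "flat"), c(0, 1, 2, 3, 4),
                          rbind(c(1, 2, 3, 2, 1), c(2, 1, 2, 3, 1),
                                c(1, 3, 1, 3, 1), c(2, 2, 2, 2, 2)))
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_warning(tri <- score_edges(delaunay_edges(coords), ds, coords),
                 "zero-variance")
  expect_false(any(tri$edges$gene_i == "flat" | tri$edges$gene_j == "flat"))
})

test_that("significance filtering is monotone in the threshold", {
  sim <- generate_synthetic(tiny_spec(seed = 3))
  n <- length(sim$dataset$gene_ids)
  set.seed(3)
  coords <- matrix(rnorm(n * 3), ncol = 3)
  tri <- score_edges(delaunay_edges(coords), sim$dataset, coords)
  all_sig <- filter_and_stats(tri, p_threshold = 1)
  expect_equal(all_sig$stats$n_significant, all_sig$stats$n_edges)
  none <- filter_and_stats(tri, p_threshold = 0)
  expect_equal(none$stats$n_significant, 0L)
  prev <- 0L
  for (thr in c(1e-6, 1e-4, 1e-2, 1)) {
    cur <- filter_and_stats(tri, p_threshold = thr)$stats$n_significant
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("significant edges are short on clustered expression data", {
  sim <- generate_synthetic(tiny_spec(seed = 4))
  res <- suppressWarnings(suppressMessages(
    run_pipeline(sim$dataset, out_dir = withr::local_tempdir(),
                 k = 4, seed = 4)))
  st <- res$triangulation$stats
  expect_gt(st$n_significant, 0L)
  expect_lte(st$mean_length_significant, st$mean_length_all)
})
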