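# Circumcenter and squared circumradius of a tetrahedron (4 x 3 matrix).
# Solves 2 (b - a) . x = |b|^2 - |a|^2 for the three edges from a reference
# vertex; the reference is chosen (trying all four) to maximize the scaled
# determinant, which keeps slivers with clustered vertices solvable. Returns
# NULL when the four points are (numerically) coplanar from every reference.
circumsphere <- function(P) {
  best <- NULL
  best_q <- 0
  for (ref in 1:4) {
    A <- 2 * (P[-ref, , drop = FALSE] - rep(P[ref, ], each = 3L))
    det_a <- det(A)
    scale <- prod(sqrt(rowSums(A^2)))
    if (!is.finite(det_a) || scale == 0) next
    q <- abs(det_a) / scale
    if (q > best_q) {
      best_q <- q
      best <- list(A = A, ref = ref)
    }
  }
  if (is.null(best) || best_q < 1e-12) return(NULL)
  ref <- best$ref
  b <- rowSums(P[-ref, , drop = FALSE]^2) - sum(P[ref, ]^2)
  ctr <- tryCatch(solve(best$A, b), error = function(e) NULL)
  if (is.null(ctr)) return(NULL)
  list(center = ctr, r2 = sum((P[ref, ] - ctr)^2))
}

# Incremental Bowyer-Watson Delaunay triangulation in 3-D.
# Returns a matrix of tetrahedra (rows of 4 vertex indices) or NULL when a
# degeneracy (coplanar insertion, inconsistent cavity) is hit.
bowyer_watson <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  rad <- sqrt(max(rowSums((pts - rep(ctr, each = n))^2)))
  if (rad == 0) return(NULL)
  # center and scale: the Delaunay complex is invariant under this affine
  # map, and unit-scale coordinates keep the circumsphere tests well
  # conditioned
  pts <- (pts - rep(ctr, each = n)) / rad
  ctr <- c(0, 0, 0)
  rad <- 1
  R <- 64 * rad
  # regular super-tetrahedron around the data
  super <- rbind(c( 1,  1,  1), c( 1, -1, -1), c(-1,  1, -1), c(-1, -1,  1))
  super <- super * R + rep(ctr, each = 4L)
  P <- rbind(pts, super)
  cap <- 16L * n + 64L
  tets <- matrix(NA_integer_, cap, 4L)
  cents <- matrix(NA_real_, cap, 3L)
  r2s <- rep(NA_real_, cap)
  alive <- rep(FALSE, cap)
  cs <- circumsphere(P[(n + 1L):(n + 4L), ])
  if (is.null(cs)) return(NULL)
  tets[1L, ] <- (n + 1L):(n + 4L)
  cents[1L, ] <- cs$center; r2s[1L] <- cs$r2; alive[1L] <- TRUE
  n_slots <- 1L
  for (p in seq_len(n)) {
    live <- which(alive[seq_len(n_slots)])
    d2 <- rowSums((cents[live, , drop = FALSE] - rep(P[p, ], each = length(live)))^2)
    bad <- live[d2 < r2s[live] * (1 + 1e-12)]
    if (length(bad) == 0L) return(NULL)          # point outside all spheres: degenerate
    # cavity boundary: faces of bad tetrahedra that appear exactly once
    faces <- matrix(0L, 4L * length(bad), 3L)
    fi <- 0L
    for (t in bad) {
      v <- tets[t, ]
      for (drop_v in 1:4) {
        fi <- fi + 1L
        faces[fi, ] <- sort(v[-drop_v])
      }
    }
    key <- paste(faces[, 1L], faces[, 2L], faces[, 3L])
    cnt <- table(key)
    boundary <- faces[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
    if (any(cnt > 2L)) return(NULL)              # inconsistent cavity
    alive[bad] <- FALSE
    for (f in seq_len(nrow(boundary))) {
      tet <- c(boundary[f, ], p)
      cs <- circumsphere(P[tet, ])
      if (is.null(cs)) return(NULL)
      slot <- if (any(!alive[seq_len(n_slots)])) which(!alive[seq_len(n_slots)])[1L] else {
        n_slots <- n_slots + 1L
        if (n_slots > cap) {                     # grow storage
          cap2 <- cap * 2L
          tets <- rbind(tets, matrix(NA_integer_, cap2 - cap, 4L))
          cents <- rbind(cents, matrix(NA_real_, cap2 - cap, 3L))
          r2s <- c(r2s, rep(NA_real_, cap2 - cap))
          alive <- c(alive, rep(FALSE, cap2 - cap))
          cap <- cap2
        }
        n_slots
      }
      tets[slot, ] <- tet
      cents[slot, ] <- cs$center; r2s[slot] <- cs$r2; alive[slot] <- TRUE
    }
  }
  keep <- which(alive[seq_len(n_slots)])
  out <- tets[keep, , drop = FALSE]
  out[rowSums(out > n) == 0L, , drop = FALSE]    # drop super-vertex tetrahedra
}

#' Delaunay edges of a 3-D point set
#'
#' Incremental (Bowyer–Watson) Delaunay triangulation of the manifold
#' coordinates; the returned edges are the union of the edges of all
#' tetrahedra. Points not in general position (duplicates, coplanar
#' configurations) are handled per `degenerate`: a deterministic jitter of
#' `1e-6` times the coordinate range is applied and the triangulation is
#' retried, or an error is raised. The jitter is a fixed quasi-random
#' sequence, so repeated runs are identical.
#'
#' @param coords G x 3 numeric matrix, G >= 4.
#' @param degenerate `"jitter"` (default) or `"error"`.
#' @return integer matrix with columns `i`, `j` (i < j), one row per edge;
#'   the attribute `"tetrahedra"` holds the simplices.
#' @export
delaunay_edges <- function(coords, degenerate = c("jitter", "error")) {
  degenerate <- match.arg(degenerate)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  G <- nrow(coords)
  if (G < 4L) stop("need at least 4 points for a 3-D triangulation")
  dup <- anyDuplicated(coords) > 0L
  tets <- if (dup) NULL else bowyer_watson(coords)
  if (is.null(tets) || nrow(tets) == 0L) {
    if (degenerate == "error")
      stop("points are not in general position (duplicates or coplanarity)")
    message("degenerate point configuration: applying deterministic jitter")
    rng <- max(apply(coords, 2L, function(x) diff(range(x))), 1e-12)
    idx <- seq_len(G)
    jit <- cbind(sin(idx * 12.9898), sin(idx * 78.233), sin(idx * 39.3468))
    tets <- bowyer_watson(coords + 1e-6 * rng * jit)
    if (is.null(tets) || nrow(tets) == 0L)
      stop("points remain degenerate after jitter (collinear or coplanar set)")
  }
  pairs <- rbind(tets[, c(1L, 2L)], tets[, c(1L, 3L)], tets[, c(1L, 4L)],
                 tets[, c(2L, 3L)], tets[, c(2L, 4L)], tets[, c(3L, 4L)])
  pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  attr(pairs, "tetrahedra") <- tets
  pairs
}

#' Attach correlation sign and significance to Delaunay edges
#'
#' For each edge, `r` is the Pearson correlation of the two genes' raw
#' expression profiles (length T), `p` the two-sided p-value from the t
#' statistic `t = r sqrt((T - 2) / (1 - r^2))` on T - 2 degrees of freedom,
#' and the sign is positive iff the correlation is. Edge length is the Euclidean
#' distance in manifold coordinates. Edges touching a zero-variance profile
#' are dropped with a warning.
#'
#' @param edges edge matrix from [delaunay_edges()].
#' @param dataset the [expression_dataset()] the coordinates came from.
#' @param coords G x 3 coordinates used for edge lengths.
#' @return Object of class `triangulation_result` with a data.frame `edges`
#'   (`gene_i`, `gene_j`, `length`, `r`, `p`, `sign`), plus `p_threshold = NA`
#'   and empty `stats` until [filter_and_stats()] runs.
#' @export
score_edges <- function(edges, dataset, coords) {
  stopifnot(inherits(dataset, "expression_dataset"))
  Tn <- length(dataset$time_stamps)
  if (Tn < 3L) stop("need at least 3 time points for edge significance")
  coords <- as.matrix(coords)
  V <- dataset$values
  i <- edges[, 1L]; j <- edges[, 2L]
  sds <- apply(V, 1L, stats::sd)
  bad <- sds[i] == 0 | sds[j] == 0
  if (any(bad)) {
    warning(sum(bad), " edge(s) dropped: zero-variance expression profile")
    i <- i[!bad]; j <- j[!bad]
  }
  r <- vapply(seq_along(i), function(e) stats::cor(V[i[e], ], V[j[e], ]),
              numeric(1L))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((Tn - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = Tn - 2)
  p <- pmax(p, .Machine$double.xmin)
  len <- sqrt(rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2))
  df <- data.frame(gene_i = dataset$gene_ids[i], gene_j = dataset$gene_ids[j],
                   length = len, r = r, p = p,
                   sign = ifelse(r > 0, "positive", "negative"),
                   stringsAsFactors = FALSE)
  structure(list(edges = df, p_threshold = NA_real_, stats = list()),
            class = "triangulation_result")
}

#' Filter scored edges by p-value and summarize lengths
#'
#' Marks edges with `p <= p_threshold` as significant and records length
#' statistics. On well-structured data the significant edges are short
#' relative to the average edge: strongly correlated genes sit close together
#' on the manifold.
#'
#' @param result a scored `triangulation_result`.
#' @param p_threshold significance cut-off (default 0.001).
#' @param adjust apply Benjamini–Hochberg adjustment before thresholding
#'   (default FALSE: raw p-values are thresholded).
#' @return The result with `p_threshold`, a logical `significant` column and
#'   `stats` (`n_edges`, `n_significant`, `mean_length_all`,
#'   `mean_length_significant`).
#' @export
filter_and_stats <- function(result, p_threshold = 0.001, adjust = FALSE) {
  stopifnot(inherits(result, "triangulation_result"))
  df <- result$edges
  pv <- if (adjust) stats::p.adjust(df$p, method = "BH") else df$p
  df$significant <- pv <= p_threshold
  result$edges <- df
  result$p_threshold <- p_threshold
  result$stats <- list(
    n_edges = nrow(df),
    n_significant = sum(df$significant),
    mean_length_all = if (nrow(df)) mean(df$length) else NA_real_,
    mean_length_significant = if (any(df$significant))
      mean(df$length[df$significant]) else NA_real_)
  result
}

#' @export
print.triangulation_result <- function(x, ...) {
  cat(sprintf("triangulation_result: %d edges", nrow(x$edges)))
  if (!is.na(x$p_threshold))
    cat(sprintf(", %d significant at p <= %g (mean length %.4g vs %.4g overall)",
                x$stats$n_significant, x$p_threshold,
                x$stats$mean_length_significant, x$stats$mean_length_all))
  cat("\n")
  invisible(x)
}
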