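#' Annotation-term over-representation in a cluster
#'
#' Upper-tail hypergeometric test for every term of an annotation map within
#' one cluster of genes: with `G_b` background genes of which `K_t` carry the
#' term, and a cluster of `n_c` genes of which `k` carry it,
#' `p = P[X >= k]` for `X ~ Hypergeometric(G_b, K_t, n_c)`. Benjamini–
#' Hochberg q-values are attached across the terms of the cluster.
#'
#' @param cluster_genes character vector of gene ids (must be a subset of the
#'   annotation background).
#' @param annotations an `annotation_map` from [read_annotations()].
#' @param cluster label recorded in the output (default `NA`).
#' @return data.frame with one row per term: `term`, `cluster`, `k`, `K_t`,
#'   `n_c`, `G_b`, `p`, `q`, sorted by increasing `p`.
#' @export
enrich <- function(cluster_genes, annotations, cluster = NA) {
  stopifnot(inherits(annotations, "annotation_map"))
  cluster_genes <- unique(as.character(cluster_genes))
  missing <- setdiff(cluster_genes, annotations$background)
  if (length(missing))
    stop("cluster gene(s) absent from annotation background: ",
         paste(missing, collapse = ", "))
  G_b <- length(annotations$background)
  n_c <- length(cluster_genes)
  rows <- lapply(names(annotations$terms), function(tm) {
    genes <- annotations$terms[[tm]]
    K_t <- length(genes)
    k <- length(intersect(genes, cluster_genes))
    # P[X >= k] with the survival form; k = 0 gives p = 1 exactly
    p <- stats::phyper(k - 1, K_t, G_b - K_t, n_c, lower.tail = FALSE)
    data.frame(term = tm, cluster = cluster, k = k, K_t = K_t,
               n_c = n_c, G_b = G_b, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p <- pmin(pmax(out$p, .Machine$double.xmin), 1)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$term), , drop = FALSE]
}

#' Enrichment for every cluster of a clustering result
#'
#' Runs [enrich()] once per cluster and stacks the rows. Genes without
#' annotations are allowed in the clustering but only genes present in the
#' background enter each test.
#'
#' @param result a `clustering_result` with named labels.
#' @param annotations an `annotation_map`.
#' @return data.frame of [enrich()] rows over all clusters.
#' @export
enrich_clusters <- function(result, annotations) {
  labs <- result$labels
  ids <- names(labs)
  if (is.null(ids)) stop("clustering result has unnamed labels")
  out <- lapply(sort(unique(labs)), function(kk) {
    genes <- intersect(ids[labs == kk], annotations$background)
    if (length(genes) == 0L) return(NULL)
    enrich(genes, annotations, cluster = kk)
  })
  do.call(rbind, out)
}
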