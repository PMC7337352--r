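#' Run the full clustering pipeline
#'
#' Chains every stage: read (or accept) an expression dataset, Haar-encode,
#' build and sparsify the similarity graph, normalize to a Markov transition
#' matrix, eigen-embed, score local dimensions, cluster with Bregman k-means
#' (fixed K, or restart-based model selection over `k_range` when `k` is
#' NULL), triangulate and filter the Delaunay network, and (optionally) test
#' annotation enrichment per cluster. All stage parameters, the seed and the
#' input digests are recorded into `scenario.txt`, making the run replayable
#' with [scenario_replay()].
#'
#' @param expression path to an expression TSV/CSV, or an
#'   [expression_dataset()] (in which case no input digest is recorded).
#' @param out_dir output directory (created if needed).
#' @param missing_policy passed to [read_expression()].
#' @param wavelet_n Haar coefficients per gene (default 64).
#' @param similarity,sigma similarity kernel, see [build_W()].
#' @param knn symmetric nearest-neighbour count (default 10).
#' @param normalization row-stochasticization method (default `"markov"`).
#' @param dims embedding dimension (default 3).
#' @param ld_neighbors,ld_tau local-dimension parameters, see
#'   [local_dimension()].
#' @param k number of clusters; NULL (default) selects K by the elbow of the
#'   mean-potential curve over `k_range`.
#' @param k_range candidate K values for model selection (default 3:15).
#' @param restarts k-means restarts (default 5).
#' @param divergence Bregman divergence (default squared Euclidean).
#' @param p_threshold Delaunay edge significance cut-off (default 0.001).
#' @param annotations optional path to an annotation TSV for per-cluster
#'   enrichment.
#' @param seed integer seed driving every stochastic stage (default 1).
#' @return Invisibly, a list with `dataset`, `features`, `graph`, `N`,
#'   `embedding`, `local_dim`, `clustering`, `selection` (NULL for fixed K),
#'   `triangulation`, `enrichment` (NULL without annotations), `scenario`,
#'   `out_dir`. Side effects: `manifold.tsv`, `clusters.tsv`, `edges.tsv`,
#'   `selection.tsv`, `enrichment.tsv`, `scenario.txt` and `run.log` in
#'   `out_dir`.
#' @export
run_pipeline <- function(expression, out_dir,
                         missing_policy = "drop_gene",
                         wavelet_n = 64L,
                         similarity = "cosine", sigma = NULL,
                         knn = 10L,
                         normalization = "markov",
                         dims = 3L,
                         ld_neighbors = 30L, ld_tau = 0.95,
                         k = NULL, k_range = 3:15, restarts = 5L,
                         divergence = "squared_euclidean",
                         p_threshold = 0.001,
                         annotations = NULL,
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
    message(...)
  }
  scn <- scenario_new()
  set.seed(seed)

  if (is.character(expression)) {
    note("reading expression table: ", expression)
    dataset <- read_expression(expression, missing_policy = missing_policy)
    scenario_record(scn, "read_expression",
                    list(path = expression, missing_policy = missing_policy),
                    inputs = expression)
  } else {
    dataset <- expression
    stopifnot(inherits(dataset, "expression_dataset"))
    scenario_record(scn, "read_expression",
                    list(path = NA, missing_policy = missing_policy))
  }
  G <- length(dataset$gene_ids)
  note("dataset: ", G, " genes x ", length(dataset$time_stamps), " time points")

  features <- encode(dataset, n = wavelet_n)
  scenario_record(scn, "encode", list(n = wavelet_n))

  graph <- build_W(features, method = similarity, sigma = sigma)
  scenario_record(scn, "build_W", list(method = similarity, sigma = sigma))
  graph <- sparsify_symmetric_knn(graph, k = knn)
  scenario_record(scn, "sparsify_symmetric_knn", list(k = knn))
  note("similarity graph: ", similarity, ", k-symmetric NN k = ", knn)

  N <- normalize_stochastic(graph, method = normalization)
  scenario_record(scn, "normalize_stochastic", list(method = normalization))
  embedding <- eigen_embed(N, d = dims)
  scenario_record(scn, "eigen_embed", list(d = dims))
  note("embedding: d = ", dims, ", eigenvalues ",
       paste(format(embedding$eigenvalues, digits = 4), collapse = " "))

  ld <- local_dimension(features, embedding$coords,
                        k_nb = ld_neighbors, tau = ld_tau)
  embedding$local_dim <- ld
  scenario_record(scn, "local_dimension",
                  list(k_nb = ld_neighbors, tau = ld_tau))

  selection <- NULL
  if (is.null(k)) {
    note("model selection over K = ", min(k_range), "..", max(k_range),
         " with ", restarts, " restarts")
    selection <- selection_curve(embedding$coords, k_range = k_range,
                                 restarts = restarts, divergence = divergence,
                                 seed = seed)
    scenario_record(scn, "selection_curve",
                    list(k_range = k_range, restarts = restarts,
                         divergence = divergence, seed = seed))
    clustering <- selection$best[[match(selection$elbow_k, selection$k)]]
    note("elbow at K = ", selection$elbow_k)
  } else {
    clustering <- bregman_kmeans(embedding$coords, K = k,
                                 divergence = divergence,
                                 restarts = restarts, seed = seed)
    scenario_record(scn, "bregman_kmeans",
                    list(k = k, restarts = restarts, divergence = divergence,
                         seed = seed))
    note("k-means: K = ", k, ", potential ",
         format(clustering$potential, digits = 6))
  }

  edges <- delaunay_edges(embedding$coords)
  scenario_record(scn, "delaunay_edges", list(degenerate = "jitter"))
  tri <- score_edges(edges, dataset, embedding$coords)
  scenario_record(scn, "score_edges", list())
  tri <- filter_and_stats(tri, p_threshold = p_threshold)
  scenario_record(scn, "filter_and_stats", list(p_threshold = p_threshold))
  note("triangulation: ", tri$stats$n_edges, " edges, ",
       tri$stats$n_significant, " significant at p <= ", p_threshold)

  enrichment <- NULL
  if (!is.null(annotations)) {
    ann <- read_annotations(annotations)
    enrichment <- enrich_clusters(clustering, ann)
    scenario_record(scn, "enrich", list(path = annotations),
                    inputs = annotations)
  }

  # ---- outputs ----------------------------------------------------------
  f_manifold <- file.path(out_dir, "manifold.tsv")
  f_clusters <- file.path(out_dir, "clusters.tsv")
  f_edges <- file.path(out_dir, "edges.tsv")
  coords_df <- data.frame(gene_id = embedding$gene_ids,
                          embedding$coords, check.names = FALSE,
                          stringsAsFactors = FALSE)
  write_table(coords_df, f_manifold)
  write_table(data.frame(gene_id = names(clustering$labels),
                         cluster = unname(clustering$labels),
                         local_dimension = unname(ld),
                         stringsAsFactors = FALSE), f_clusters)
  write_table(tri$edges, f_edges)
  outputs <- c(f_manifold, f_clusters, f_edges)
  if (!is.null(selection)) {
    f_sel <- file.path(out_dir, "selection.tsv")
    write_table(data.frame(k = selection$k,
                           mean_potential = selection$mean_potential,
                           sd_potential = selection$sd_potential), f_sel)
    outputs <- c(outputs, f_sel)
  }
  if (!is.null(enrichment)) {
    f_enr <- file.path(out_dir, "enrichment.tsv")
    write_table(enrichment, f_enr)
    outputs <- c(outputs, f_enr)
  }
  scenario_record(scn, "write_outputs", list(), outputs = outputs)
  scenario_save(scn, file.path(out_dir, "scenario.txt"))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(dataset = dataset, features = features, graph = graph,
                 N = N, embedding = embedding, local_dim = ld,
                 clustering = clustering, selection = selection,
                 triangulation = tri, enrichment = enrichment,
                 scenario = scn, out_dir = out_dir))
}
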