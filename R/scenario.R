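REGISTERED_OPS <- c(
  "read_expression", "generate_synthetic", "encode", "build_W",
  "sparsify_symmetric_knn", "normalize_stochastic", "eigen_embed",
  "local_dimension", "selection_curve", "bregman_kmeans", "nnmf_cluster",
  "affinity_propagation", "delaunay_edges", "score_edges", "filter_and_stats",
  "enrich", "write_outputs")

#' Start a new analysis scenario
#'
#' A scenario is an ordered record of every pipeline operation executed, with
#' its full parameter map (seeds included) and MD5 digests of the files it
#' read and wrote. Saved scenarios are plain text and can be replayed to
#' reproduce an analysis exactly.
#'
#' @return An environment of class `scenario` with fields `records` (list)
#'   and `version`.
#' @export
scenario_new <- function() {
  scn <- new.env(parent = emptyenv())
  scn$records <- list()
  scn$version <- as.character(utils::packageVersion("wavemap"))
  class(scn) <- "scenario"
  scn
}

# canonical JSON-stable form so save/load round-trips are identities
canonical_params <- function(params) {
  jsonlite::fromJSON(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA,
                                      null = "null"),
                     simplifyVector = TRUE)
}

#' Append an operation record to a scenario
#'
#' @param scn a [scenario_new()] environment.
#' @param op name of the executed operation (must be a registered pipeline
#'   operation).
#' @param params named list of the parameters used, including any seed.
#' @param inputs,outputs character vectors of file paths; their MD5 digests
#'   are stored so silent input drift is detectable at replay time.
#' @return the scenario, invisibly.
#' @export
scenario_record <- function(scn, op, params = list(),
                            inputs = character(0), outputs = character(0)) {
  stopifnot(inherits(scn, "scenario"))
  if (!op %in% REGISTERED_OPS) stop("unregistered operation: ", op)
  digest_of <- function(paths) {
    if (length(paths) == 0L) return(list())
    d <- as.list(unname(tools::md5sum(paths)))
    names(d) <- basename(paths)
    d
  }
  rec <- list(step = length(scn$records) + 1L, op = op,
              params = canonical_params(params),
              inputs = digest_of(inputs), input_paths = as.character(inputs),
              outputs = digest_of(outputs))
  scn$records[[rec$step]] <- rec
  invisible(scn)
}

#' Save a scenario to a line-oriented text file
#'
#' One record per line: `step<TAB>op<TAB>JSON payload` (parameters, input
#' paths and digests, output digests), preceded by a `#wavemap-scenario`
#' header carrying the tool version.
#'
#' @param scn a scenario.
#' @param path output path.
#' @export
scenario_save <- function(scn, path) {
  stopifnot(inherits(scn, "scenario"))
  lines <- c(paste0("#wavemap-scenario\t", scn$version))
  for (rec in scn$records) {
    payload <- jsonlite::toJSON(rec[c("params", "inputs", "input_paths",
                                      "outputs")],
                                auto_unbox = TRUE, digits = NA, null = "null")
    lines <- c(lines, paste(rec$step, rec$op, payload, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a scenario from disk
#'
#' @param path a file written by [scenario_save()].
#' @return a `scenario` environment; malformed lines and unknown operation
#'   names raise an error naming the offending line.
#' @export
scenario_load <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1L], "#wavemap-scenario"))
    stop("not a wavemap scenario file: ", path)
  scn <- scenario_new()
  scn$version <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][2L]
  body <- lines[-1L]
  for (ln in seq_along(body)) {
    parts <- strsplit(body[ln], "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 3L)
      stop("malformed scenario line ", ln + 1L)
    step <- suppressWarnings(as.integer(parts[1L]))
    if (is.na(step) || step != ln)
      stop("non-contiguous step index at line ", ln + 1L)
    if (!parts[2L] %in% REGISTERED_OPS)
      stop("unknown operation '", parts[2L], "' at line ", ln + 1L)
    payload <- tryCatch(jsonlite::fromJSON(parts[3L], simplifyVector = TRUE),
                        error = function(e)
                          stop("malformed scenario line ", ln + 1L, ": ",
                               conditionMessage(e)))
    scn$records[[step]] <- list(step = step, op = parts[2L],
                                params = as.list(payload$params),
                                inputs = as.list(payload$inputs),
                                input_paths = as.character(payload$input_paths),
                                outputs = as.list(payload$outputs))
  }
  scn
}

#' Replay a recorded pipeline scenario
#'
#' Re-executes the full pipeline with the parameters stored in the scenario.
#' Input files are re-digested first; a mismatch with the recorded digest is
#' a warning (or an error with `strict = TRUE`). Deterministic stages
#' reproduce byte-identical outputs; stochastic stages reproduce identical
#' outputs because their recorded seeds are reused.
#'
#' @param scn a scenario (or a path to one).
#' @param out_dir directory for the replayed outputs.
#' @param expression optional replacement path for the expression input;
#'   defaults to the recorded path.
#' @param strict error (rather than warn) on input digest mismatch.
#' @return the [run_pipeline()] result list, invisibly.
#' @export
scenario_replay <- function(scn, out_dir, expression = NULL, strict = FALSE) {
  if (is.character(scn)) scn <- scenario_load(scn)
  stopifnot(inherits(scn, "scenario"))
  ops <- vapply(scn$records, `[[`, character(1L), "op")
  pick <- function(op) {
    i <- which(ops == op)
    if (length(i) == 0L) NULL else scn$records[[i[1L]]]
  }
  read_rec <- pick("read_expression")
  if (is.null(read_rec)) stop("scenario does not contain a pipeline run")
  path <- expression %||% read_rec$input_paths[1L]
  if (!file.exists(path)) stop("expression input not found: ", path)
  recorded <- read_rec$inputs[[1L]]
  if (!is.null(recorded)) {
    now <- unname(tools::md5sum(path))
    if (!identical(now, recorded)) {
      msg <- paste0("input digest mismatch for ", path,
                    " (recorded ", recorded, ", found ", now, ")")
      if (strict) stop(msg) else warning(msg)
    }
  }
  p <- function(op, name, default) {
    rec <- pick(op)
    if (is.null(rec) || is.null(rec$params[[name]])) default else rec$params[[name]]
  }
  km <- pick("bregman_kmeans"); sel <- pick("selection_curve")
  run_pipeline(
    expression = path, out_dir = out_dir,
    missing_policy = p("read_expression", "missing_policy", "drop_gene"),
    wavelet_n = p("encode", "n", 64L),
    similarity = p("build_W", "method", "cosine"),
    sigma = p("build_W", "sigma", NULL),
    knn = p("sparsify_symmetric_knn", "k", 10L),
    normalization = p("normalize_stochastic", "method", "markov"),
    dims = p("eigen_embed", "d", 3L),
    ld_neighbors = p("local_dimension", "k_nb", 30L),
    ld_tau = p("local_dimension", "tau", 0.95),
    k = if (is.null(km)) NULL else km$params$k,
    k_range = if (is.null(sel)) 3:15 else sel$params$k_range,
    restarts = p("bregman_kmeans", "restarts",
                 p("selection_curve", "restarts", 5L)),
    divergence = p("bregman_kmeans", "divergence", "squared_euclidean"),
    p_threshold = p("filter_and_stats", "p_threshold", 0.001),
    annotations = {
      er <- pick("enrich")
      if (is.null(er)) NULL else er$input_paths[1L]
    },
    seed = p("bregman_kmeans", "seed", p("selection_curve", "seed", 1L)))
}
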