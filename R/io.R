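#' Construct an expression dataset
#'
#' Container for a gene-by-time-point expression matrix with ordered time
#' stamps in minutes. This is the raw input to the whole pipeline.
#'
#' @param gene_ids character vector of unique gene/probe identifiers.
#' @param time_stamps strictly increasing numeric vector of time stamps
#'   (minutes), one per column of `values`.
#' @param values numeric matrix, genes in rows, time points in columns.
#' @param meta optional named list of free-form header information.
#'
#' @return An object of class `expression_dataset` with fields `gene_ids`,
#'   `time_stamps`, `values` (with dimnames set) and `meta`.
#' @export
expression_dataset <- function(gene_ids, time_stamps, values, meta = list()) {
  gene_ids <- as.character(gene_ids)
  time_stamps <- as.numeric(time_stamps)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(gene_ids) < 2L) stop("need at least 2 genes, got ", length(gene_ids))
  if (length(time_stamps) < 2L) stop("need at least 2 time points, got ", length(time_stamps))
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(time_stamps))) stop("non-numeric or non-finite time stamp")
  if (any(diff(time_stamps) <= 0)) stop("time stamps must be strictly increasing")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(time_stamps))
    stop("values matrix must be genes x time points (",
         length(gene_ids), " x ", length(time_stamps), ")")
  if (anyNA(values)) stop("values contain missing entries; apply a missing policy first")
  dimnames(values) <- list(gene_ids, format(time_stamps, trim = TRUE))
  structure(list(gene_ids = gene_ids, time_stamps = time_stamps,
                 values = values, meta = meta),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d time points (%.6g..%.6g min)\n",
              length(x$gene_ids), length(x$time_stamps),
              x$time_stamps[1L], x$time_stamps[length(x$time_stamps)]))
  invisible(x)
}

# tab first, comma fallback
sniff_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("empty file: ", path)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a gene-by-time expression table
#'
#' Reads a TSV/CSV file whose first column holds gene identifiers and whose
#' header row holds numeric time stamps (minutes). The delimiter is sniffed
#' (tab first, comma fallback). Empty cells, `NA` and `NaN` are treated as
#' missing; missing values are handled per `missing_policy` and the number of
#' affected genes is reported with a message.
#'
#' @param path path to the expression table.
#' @param missing_policy `"drop_gene"` removes any gene with a missing value;
#'   `"interpolate"` fills gaps by linear interpolation along the gene's own
#'   time course (nearest value at the ends).
#'
#' @return An [expression_dataset()]. If the header labels are not numeric the
#'   time stamps fall back to `0..T-1` with a warning.
#' @export
read_expression <- function(path, missing_policy = c("drop_gene", "interpolate")) {
  missing_policy <- match.arg(missing_policy)
  delim <- sniff_delim(path)
  tab <- utils::read.table(path, sep = delim, header = TRUE, check.names = FALSE,
                           colClasses = "character", comment.char = "",
                           na.strings = c("", "NA", "NaN"), quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("need at least 2 time-point columns, got ", ncol(tab) - 1L)
  gene_ids <- as.character(tab[[1L]])
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  }
  hdr <- colnames(tab)[-1L]
  time_stamps <- suppressWarnings(as.numeric(hdr))
  if (anyNA(time_stamps)) {
    warning("non-numeric time-stamp header; falling back to uniform stamps 0..T-1")
    time_stamps <- seq_len(length(hdr)) - 1
  } else if (any(diff(time_stamps) <= 0)) {
    stop("non-numeric time stamp header: stamps not strictly increasing")
  }
  vals <- suppressWarnings(vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
  vals <- matrix(as.numeric(vals), nrow = nrow(tab),
                 dimnames = list(gene_ids, hdr))
  bad <- which(apply(vals, 1L, anyNA))
  if (length(bad)) {
    if (missing_policy == "drop_gene") {
      message(length(bad), " gene(s) dropped for missing values")
      vals <- vals[-bad, , drop = FALSE]
      gene_ids <- gene_ids[-bad]
    } else {
      for (i in bad) {
        ok <- which(!is.na(vals[i, ]))
        if (length(ok) < 2L)
          stop("gene ", gene_ids[i], " has fewer than 2 observed values; cannot interpolate")
        vals[i, ] <- stats::approx(time_stamps[ok], vals[i, ok],
                                   xout = time_stamps, rule = 2)$y
      }
      message(length(bad), " gene(s) repaired by linear interpolation")
    }
  }
  expression_dataset(gene_ids, time_stamps, vals)
}

#' Read a gene-to-term annotation map
#'
#' Two-column tab-separated file, `gene<TAB>term`, one pair per line. Blank
#' lines are skipped with a message. The background set is the set of all
#' genes seen in the file.
#'
#' @param path path to the annotation TSV.
#' @return A list of class `annotation_map` with `terms` (named list of
#'   character vectors, term -> gene ids) and `background` (character vector).
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    message(sum(blank), " blank line(s) skipped")
    lines <- lines[!blank]
  }
  if (length(lines) == 0L) stop("empty annotation file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop("malformed annotation line(s): ", paste(which(nf != 2L), collapse = ", "))
  gene <- vapply(parts, `[[`, character(1L), 1L)
  term <- vapply(parts, `[[`, character(1L), 2L)
  terms <- lapply(split(gene, term), unique)
  structure(list(terms = terms, background = unique(gene)),
            class = "annotation_map")
}

#' Write a tabular result file
#'
#' Tab-separated, header row, no quoting, no row names; numeric columns keep
#' full double precision so a write/read round trip is lossless to 1e-9.
#'
#' @param rows a data.frame of records (may have zero rows: a header-only file
#'   is written).
#' @param path output path.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  num <- vapply(rows, is.numeric, logical(1L))
  out <- rows
  out[num] <- lapply(rows[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write an expression dataset as a TSV table
#'
#' First column `gene_id`, remaining columns named by the time stamps;
#' readable back with [read_expression()].
#'
#' @param dataset an [expression_dataset()].
#' @param path output path.
#' @export
write_expression <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  df <- data.frame(gene_id = dataset$gene_ids, dataset$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", format(dataset$time_stamps, trim = TRUE, digits = 15))
  write_table(df, path)
}

#' Read back a table written by [write_table()]
#'
#' @param path path to the TSV file.
#' @return data.frame with types inferred.
#' @export
read_table_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "", quote = "\"")
}
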