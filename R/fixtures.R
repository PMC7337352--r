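#' Specification of a synthetic periodic expression dataset
#'
#' Describes a yeast-metabolic-cycle-like design: several groups of periodic,
#' phase-shifted genes observed over repeated cycles, plus a population of
#' aperiodic genes, with additive Gaussian noise. The defaults mirror a
#' three-phase oscillating culture sampled 36 times over 300 minutes across
#' 3 cycles, with roughly a third of the genes periodic.
#'
#' @param n_groups number of periodic phase groups (default 3).
#' @param genes_per_group genes per periodic group (default 50).
#' @param n_aperiodic number of aperiodic genes (default 150).
#' @param n_time time points (default 36).
#' @param n_cycles full cycles spanned by the time course (default 3).
#' @param total_minutes span of the time course (default 300).
#' @param noise_sd additive noise standard deviation (default 0.2).
#' @param amplitude length-2 range of per-gene amplitudes (default c(1, 2)).
#' @param n_sentinels noiseless "core" sentinel genes at the head of each
#'   periodic group (default 10); their profiles carry no additive noise,
#'   mimicking experimentally validated phase markers.
#' @param seed RNG seed (default 1).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_groups = 3L, genes_per_group = 50L,
                           n_aperiodic = 150L, n_time = 36L, n_cycles = 3L,
                           total_minutes = 300, noise_sd = 0.2,
                           amplitude = c(1, 2), n_sentinels = 10L, seed = 1L) {
  stopifnot(n_groups >= 1L, genes_per_group >= 1L, n_aperiodic >= 0L,
            n_time >= 2L, n_cycles >= 1L, total_minutes > 0, noise_sd >= 0,
            length(amplitude) == 2L, amplitude[1L] > 0,
            amplitude[2L] >= amplitude[1L],
            n_sentinels >= 0L, n_sentinels <= genes_per_group)
  structure(list(n_groups = as.integer(n_groups),
                 genes_per_group = as.integer(genes_per_group),
                 n_aperiodic = as.integer(n_aperiodic),
                 n_time = as.integer(n_time), n_cycles = as.integer(n_cycles),
                 total_minutes = total_minutes, noise_sd = noise_sd,
                 amplitude = amplitude, n_sentinels = as.integer(n_sentinels),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# moving-average smoothing with reflected ends
smooth_ma <- function(x, window = 5L) {
  half <- window %/% 2L
  padded <- c(rev(x[seq_len(half)]), x, rev(x[length(x) - seq_len(half) + 1L]))
  as.numeric(stats::filter(padded, rep(1 / window, window), sides = 2L))[
    half + seq_along(x)]
}

#' Generate a synthetic dataset with ground-truth labels
#'
#' Periodic group g gets profiles
#' `a * sin(2*pi*n_cycles*t/total + phi_g) + eps`, with the group phase
#' `phi_g = 2*pi*(g-1)/n_groups`, per-gene amplitude `a` uniform in the
#' amplitude range and `eps ~ N(0, noise_sd^2)`; the first `n_sentinels`
#' genes of each group are generated without noise. Aperiodic genes are
#' standardized smoothed Gaussian random walks. Regeneration under the same
#' spec (seed included) is byte-identical.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (an [expression_dataset()]), `labels` (named
#'   integer vector: group 1..n_groups, 0 for aperiodic) and `sentinels`
#'   (named list of sentinel gene-id sets, one per periodic group).
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  # exclusive endpoint: the cycle length is then an exact number of sampling
  # steps whenever n_time is a multiple of n_cycles, so noiseless profiles
  # repeat exactly across cycles
  t <- (seq_len(spec$n_time) - 1) * spec$total_minutes / spec$n_time
  omega <- 2 * pi * spec$n_cycles / spec$total_minutes
  profiles <- list(); ids <- character(0); labels <- integer(0)
  sentinels <- list()
  for (g in seq_len(spec$n_groups)) {
    phi <- 2 * pi * (g - 1) / spec$n_groups
    base <- sin(omega * t + phi)
    gid <- sprintf("grp%d_g%03d", g, seq_len(spec$genes_per_group))
    for (i in seq_len(spec$genes_per_group)) {
      a <- stats::runif(1L, spec$amplitude[1L], spec$amplitude[2L])
      eps <- if (i <= spec$n_sentinels) 0 else
        stats::rnorm(spec$n_time, 0, spec$noise_sd)
      profiles[[length(profiles) + 1L]] <- a * base + eps
    }
    ids <- c(ids, gid)
    labels <- c(labels, rep(g, spec$genes_per_group))
    if (spec$n_sentinels > 0L)
      sentinels[[paste0("group", g)]] <- gid[seq_len(spec$n_sentinels)]
  }
  if (spec$n_aperiodic > 0L) {
    gid <- sprintf("aper_g%03d", seq_len(spec$n_aperiodic))
    for (i in seq_len(spec$n_aperiodic)) {
      a <- stats::runif(1L, spec$amplitude[1L], spec$amplitude[2L])
      w <- smooth_ma(cumsum(stats::rnorm(spec$n_time)), 5L)
      w <- (w - mean(w)) / max(stats::sd(w), 1e-12) * a / sqrt(2)
      profiles[[length(profiles) + 1L]] <-
        w + stats::rnorm(spec$n_time, 0, spec$noise_sd)
    }
    ids <- c(ids, gid)
    labels <- c(labels, rep(0L, spec$n_aperiodic))
  }
  values <- do.call(rbind, profiles)
  names(labels) <- ids
  list(dataset = expression_dataset(ids, t, values,
                                    meta = list(generator = "wavemap synthetic",
                                                seed = spec$seed)),
       labels = labels, sentinels = sentinels)
}

#' Sentinel co-assignment report
#'
#' For each sentinel set (a group of genes known to be co-regulated), reports
#' the percentage assigned to the set's majority cluster ("correct") and the
#' complementary percentage spread over other clusters ("collision"). A set
#' entirely inside one cluster scores correct = 100, collision = 0.
#'
#' @param labels named integer vector of cluster assignments.
#' @param sentinel_sets named list of character vectors of gene ids.
#' @return data.frame with `set`, `n`, `majority_cluster`, `correct`,
#'   `collision` (percentages).
#' @export
sentinel_report <- function(labels, sentinel_sets) {
  ids <- names(labels)
  if (is.null(ids)) stop("labels must be named by gene id")
  rows <- lapply(names(sentinel_sets), function(nm) {
    genes <- sentinel_sets[[nm]]
    unknown <- setdiff(genes, ids)
    if (length(unknown))
      stop("unknown sentinel id(s) in set ", nm, ": ",
           paste(unknown, collapse = ", "))
    tab <- table(labels[genes])
    correct <- 100 * max(tab) / length(genes)
    data.frame(set = nm, n = length(genes),
               majority_cluster = as.integer(names(tab)[which.max(tab)]),
               correct = correct, collision = 100 - correct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
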