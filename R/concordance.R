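#' Size of the intersection of two DE gene sets
#' @param de_a,de_b Character vectors of gene ids.
#' @return Integer overlap.
#' @export
pairwise_overlap <- function(de_a, de_b) {
  length(intersect(unique(de_a), unique(de_b)))
}

#' Resampling null for the overlap of two DE gene sets
#'
#' Each draw samples `n_a` genes uniformly without replacement from cell line
#' A's expressed genes and, independently, `n_b` from cell line B's expressed
#' genes, and records the intersection size. Returns the mean and SD
#' (population denominator `n_draws` — the z-score is a descriptive
#' standardization) of the null overlap.
#'
#' @param expressed_a,expressed_b Expressed-gene universes of the two lines.
#' @param n_a,n_b Numbers of genes to draw (the observed DE-set sizes).
#' @param n_draws Number of random draws (default 10000).
#' @param seed Integer seed; results are reproducible given `(seed, n_draws)`.
#' @return List with `null_mean`, `null_sd`, `draws` (the overlap sizes).
#' @export
overlap_null <- function(expressed_a, expressed_b, n_a, n_b,
                         n_draws = 10000L, seed = 1L) {
  expressed_a <- unique(expressed_a); expressed_b <- unique(expressed_b)
  if (n_a > length(expressed_a) || n_b > length(expressed_b)) {
    stop("cannot draw more genes than the expressed universe contains")
  }
  if (n_draws < 1L) stop("n_draws must be >= 1")
  draws <- withr::with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      a <- sample(expressed_a, n_a)
      b <- sample(expressed_b, n_b)
      length(intersect(a, b))
    }, integer(1))
  })
  m <- mean(draws)
  list(null_mean = m, null_sd = sqrt(mean((draws - m)^2)), draws = draws)
}

#' Pairwise DE-set overlap z-scores across cell lines
#'
#' For every unordered pair of cell lines, compares the observed overlap of
#' their DE gene sets with the resampling null of [overlap_null()] drawn
#' from each line's expressed genes. Pairs where either DE set is empty get
#' `z = NA`.
#'
#' @param de_sets Named list of DE gene-id vectors, one per cell line.
#' @param expressed_sets Named list of expressed gene-id vectors (same names).
#' @param n_draws Draws per pair (default 10000).
#' @param seed Master seed; each pair uses a seed derived from it.
#' @return Data frame with one row per pair: `cell_line_a`, `cell_line_b`,
#'   `observed`, `null_mean`, `null_sd`, `z`, `n_draws`.
#' @export
overlap_zscores <- function(de_sets, expressed_sets, n_draws = 10000L,
                            seed = 1L) {
  lines <- names(de_sets)
  if (length(lines) < 2L) stop("need at least two cell lines")
  if (!all(lines %in% names(expressed_sets))) {
    stop("expressed_sets must cover every cell line in de_sets")
  }
  pairs <- utils::combn(lines, 2L, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    obs <- pairwise_overlap(de_sets[[a]], de_sets[[b]])
    n_a <- length(unique(de_sets[[a]])); n_b <- length(unique(de_sets[[b]]))
    if (min(n_a, n_b) == 0L) {
      return(data.frame(cell_line_a = a, cell_line_b = b, observed = obs,
                        null_mean = NA_real_, null_sd = NA_real_,
                        z = NA_real_, n_draws = 0L,
                        stringsAsFactors = FALSE))
    }
    nul <- overlap_null(expressed_sets[[a]], expressed_sets[[b]], n_a, n_b,
                        n_draws = n_draws, seed = derive_seed(seed, i))
    data.frame(cell_line_a = a, cell_line_b = b, observed = obs,
               null_mean = nul$null_mean, null_sd = nul$null_sd,
               z = if (nul$null_sd > 0) (obs - nul$null_mean) / nul$null_sd
                   else NA_real_,
               n_draws = n_draws, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Direction-of-change concordance summaries
#'
#' For each cell line, averages the per-gene direction indicator (1 = higher
#' normalized mean after treatment, 0 = lower; NA excluded) over several gene
#' classes: all tested genes, genes DE in at least one cell line, and strata
#' of genes DE in exactly `k` cell lines for `k >= 2`. Under a null in which
#' treatment does nothing, all means concentrate around 0.5; shared, sign-
#' concordant responses push the strata means toward 0 or 1.
#'
#' @param de_results Named list of [run_de()] results, one per cell line.
#' @return Data frame with `cell_line`, `gene_class`, `mean_indicator`,
#'   `n_genes`.
#' @export
direction_summary <- function(de_results) {
  lines <- names(de_results)
  de_sets <- lapply(de_results, `[[`, "de_genes")
  counts <- table(unlist(de_sets, use.names = FALSE))
  genes_ge1 <- names(counts)
  kmax <- if (length(counts)) max(counts) else 0L

  rows <- list()
  for (cl in lines) {
    res <- de_results[[cl]]$results
    dir <- res$direction
    names(dir) <- res$gene_id
    add <- function(class, ids) {
      v <- dir[intersect(ids, names(dir))]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <<- data.frame(
        cell_line = cl, gene_class = class,
        mean_indicator = if (length(v)) mean(v) else NA_real_,
        n_genes = length(v), stringsAsFactors = FALSE)
    }
    add("all_genes", res$gene_id)
    add("de_ge_1", genes_ge1)
    if (kmax >= 2L) for (k in 2:kmax) {
      add(sprintf("de_in_%d", k), names(counts)[counts == k])
    }
  }
  do.call(rbind, rows)
}

#' Empirical p-value for overlap with an external gene list
#'
#' Compares the observed overlap between a foreground set (e.g. genes DE in
#' two or more cell lines) and an external reference list (e.g. promoter-
#' binding genes from ChIP) against random foregrounds of the same size drawn
#' without replacement from the expressed universe. The empirical p-value is
#' the fraction of draws whose overlap is at least the observed one
#' (`>=` rule; configurable to strict `>`).
#'
#' @param foreground Gene ids of the observed foreground.
#' @param reference_list External gene ids.
#' @param universe Gene ids eligible for random foregrounds.
#' @param n_draws Number of random sets (default 1000).
#' @param seed Integer seed.
#' @param strict If `TRUE`, count draws with overlap strictly greater than
#'   observed (default `FALSE`, the `>=` rule).
#' @return List with `observed`, `n_draws`, `n_ge_observed`, `empirical_p`,
#'   `seed`.
#' @export
list_overlap_empirical_p <- function(foreground, reference_list, universe,
                                     n_draws = 1000L, seed = 1L,
                                     strict = FALSE) {
  foreground <- unique(foreground); universe <- unique(universe)
  reference_list <- unique(reference_list)
  if (length(foreground) > length(universe)) {
    stop("foreground larger than universe")
  }
  observed <- pairwise_overlap(foreground, reference_list)
  ref_in_univ <- intersect(reference_list, universe)
  hits <- withr::with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      length(intersect(sample(universe, length(foreground)), ref_in_univ))
    }, integer(1))
  })
  n_ge <- if (strict) sum(hits > observed) else sum(hits >= observed)
  list(observed = observed, n_draws = n_draws, n_ge_observed = n_ge,
       empirical_p = n_ge / n_draws, seed = seed)
}
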