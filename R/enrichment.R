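#' Upper-tail hypergeometric p-value for category over-representation
#'
#' `P(X >= n_overlap)` with `X ~ Hypergeom(n_universe, n_category,
#' n_foreground)`: the chance that a random foreground of the given size
#' captures at least as many category genes as observed.
#'
#' @param n_universe Universe size.
#' @param n_category Category genes in the universe.
#' @param n_foreground Foreground size.
#' @param n_overlap Observed category genes in the foreground.
#' @return p-value in `(0, 1]`.
#' @export
hypergeom_p <- function(n_universe, n_category, n_foreground, n_overlap) {
  if (n_category > n_universe || n_foreground > n_universe ||
      n_overlap > min(n_category, n_foreground) || n_overlap < 0) {
    stop("inconsistent hypergeometric counts")
  }
  stats::phyper(n_overlap - 1, n_category, n_universe - n_category,
                n_foreground, lower.tail = FALSE)
}

# Logical membership matrix (universe genes x categories) for a named list
# of category gene sets, restricted to the universe.
membership_matrix <- function(annotations, universe) {
  memb <- vapply(annotations, function(g) universe %in% g,
                 logical(length(universe)))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = length(universe))
  dimnames(memb) <- list(universe, names(annotations))
  memb
}

#' Permutation (min-p) family-wise error criterion for category p-values
#'
#' Draws `n_perms` random foregrounds of the observed size from the universe
#' and records, for each, the minimum hypergeometric p over all categories in
#' the family (Westfall-Young style). A category meets the FWER criterion
#' when the fraction of permutations whose minimum p is at most its own p
#' falls below `fwer_threshold`.
#'
#' @param p Named vector of observed category p-values (the family).
#' @param annotations Named list of category gene sets (same names as `p`).
#' @param foreground,universe Gene-id vectors; random foregrounds match
#'   `length(foreground)`.
#' @param n_perms Number of random foregrounds (default 1000).
#' @param seed Integer seed.
#' @param fwer_threshold Family-wise error cutoff (default 0.1).
#' @return Data frame with `category_id`, `fwer` (the min-p exceedance
#'   fraction) and `fwer_ok`.
#' @export
fwer_adjust <- function(p, annotations, foreground, universe,
                        n_perms = 1000L, seed = 1L, fwer_threshold = 0.1) {
  universe <- unique(universe); foreground <- unique(foreground)
  if (length(foreground) > length(universe)) {
    stop("foreground larger than universe")
  }
  if (n_perms < 1L) stop("n_perms must be >= 1")
  stopifnot(all(names(p) %in% names(annotations)))
  ann <- lapply(annotations[names(p)], intersect, universe)
  memb <- membership_matrix(ann, universe)
  n_cat <- colSums(memb)
  n_univ <- length(universe)
  n_fg <- length(foreground)

  min_p <- withr::with_seed(seed, {
    vapply(seq_len(n_perms), function(i) {
      idx <- sample.int(n_univ, n_fg)
      ov <- colSums(memb[idx, , drop = FALSE])
      min(stats::phyper(ov - 1, n_cat, n_univ - n_cat, n_fg,
                        lower.tail = FALSE))
    }, numeric(1))
  })
  fwer <- vapply(p, function(pc) mean(min_p <= pc), numeric(1))
  data.frame(category_id = names(p), fwer = fwer,
             fwer_ok = fwer < fwer_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Redundancy and minimum-size pruning of enrichment results
#'
#' Two rules: (1) categories with fewer than `min_size` genes in the
#' analysis universe are pruned as `too_small`; (2) scanning the significant
#' categories in ascending-p order (ties broken by category id), a category
#' is pruned as `redundant` when more than `redundancy` (a fraction) of its
#' universe genes lie in the union of already-retained significant
#' categories with strictly lower p. Pruned categories never accumulate into
#' that union, and pruned categories are never reported significant.
#'
#' @param results Data frame with at least `category_id`, `p`,
#'   `significant`.
#' @param annotations Named list of category gene sets.
#' @param universe Gene-id vector defining the analysis universe.
#' @param min_size Minimum universe genes per category (default 5).
#' @param redundancy Fraction above which overlap with retained significant
#'   categories prunes a category (default 0.9).
#' @return `results` with `pruned` and `prune_reason` columns added and
#'   `significant` forced `FALSE` for pruned categories, sorted by
#'   `(p, category_id)`.
#' @export
prune_categories <- function(results, annotations, universe, min_size = 5L,
                             redundancy = 0.9) {
  universe <- unique(universe)
  ann <- lapply(annotations[results$category_id], intersect, universe)
  results$pruned <- FALSE
  results$prune_reason <- "none"

  small <- vapply(ann, length, integer(1)) < min_size
  results$pruned[small] <- TRUE
  results$prune_reason[small] <- "too_small"

  ord <- order(results$p, results$category_id)
  results <- results[ord, , drop = FALSE]
  ann <- ann[results$category_id]

  retained_union <- character(0)
  pending <- list()   # retained at the current p, not yet in the union
  last_p <- -Inf
  for (i in seq_len(nrow(results))) {
    if (!results$significant[i] || results$pruned[i]) next
    if (results$p[i] > last_p) {
      retained_union <- union(retained_union, unlist(pending))
      pending <- list()
      last_p <- results$p[i]
    }
    genes <- ann[[i]]
    if (length(genes) &&
        length(intersect(genes, retained_union)) / length(genes) > redundancy) {
      results$pruned[i] <- TRUE
      results$prune_reason[i] <- "redundant"
    } else {
      pending <- c(pending, list(genes))
    }
  }
  results$significant <- results$significant & !results$pruned
  rownames(results) <- NULL
  results
}

#' Hypergeometric category enrichment with FWER control and pruning
#'
#' Per category: the upper-tail hypergeometric p for over-representation of
#' the category's universe genes in the foreground. A category is significant
#' when `p < p_threshold` and it meets the permutation FWER criterion; the
#' minimum-size and redundancy pruning rules are then applied.
#'
#' @param foreground Gene ids (must be a subset of `universe`).
#' @param universe Gene ids of the analysis universe.
#' @param annotations Named list of category gene sets (pre-propagated).
#' @param p_threshold Significance cutoff on the raw p (default 0.1).
#' @param fwer_threshold Family-wise error cutoff (default 0.1).
#' @param min_size,redundancy Pruning parameters (defaults 5 and 0.9).
#' @param n_perms Permutations for the FWER criterion (default 1000).
#' @param seed Integer seed.
#' @return Data frame with one row per category: counts, `p`, `fwer`,
#'   `significant`, `pruned`, `prune_reason`, sorted by `(p, category_id)`.
#' @export
run_enrichment <- function(foreground, universe, annotations,
                           p_threshold = 0.1, fwer_threshold = 0.1,
                           min_size = 5L, redundancy = 0.9,
                           n_perms = 1000L, seed = 1L) {
  universe <- unique(universe); foreground <- unique(foreground)
  if (length(universe) == 0L) stop("empty universe")
  if (!all(foreground %in% universe)) {
    stop("foreground must be a subset of the universe")
  }
  ann <- lapply(annotations, intersect, universe)
  n_cat <- vapply(ann, length, integer(1))
  n_ov <- vapply(ann, function(g) length(intersect(g, foreground)),
                 integer(1))
  p <- stats::phyper(n_ov - 1, n_cat, length(universe) - n_cat,
                     length(foreground), lower.tail = FALSE)
  names(p) <- names(ann)

  results <- data.frame(category_id = names(ann),
                        n_category_in_universe = n_cat,
                        n_category_in_foreground = n_ov,
                        p = p, stringsAsFactors = FALSE, row.names = NULL)

  # FWER family = categories passing the size filter.
  family <- results$category_id[results$n_category_in_universe >= min_size]
  results$fwer <- NA_real_
  fwer_ok <- stats::setNames(rep(FALSE, nrow(results)), results$category_id)
  if (length(family) && length(foreground)) {
    fw <- fwer_adjust(p[family], annotations, foreground, universe,
                      n_perms = n_perms, seed = seed,
                      fwer_threshold = fwer_threshold)
    results$fwer[match(fw$category_id, results$category_id)] <- fw$fwer
    fwer_ok[fw$category_id] <- fw$fwer_ok
  }
  results$significant <- results$p < p_threshold &
    fwer_ok[results$category_id]

  prune_categories(results, annotations, universe, min_size = min_size,
                   redundancy = redundancy)
}
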