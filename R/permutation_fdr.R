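#' Enumerate all non-identity treated/control relabelings
#'
#' All `choose(n_treated + n_control, n_control)` ways to pick which samples
#' play the control role, minus the true assignment, in deterministic order
#' (combinations enumerated lexicographically over samples sorted by id).
#'
#' @param sample_ids Sample ids of the cell line.
#' @param true_control Sample ids holding the control label in the real data.
#' @return List of character vectors, each the control-sample set of one
#'   relabeling.
#' @export
enumerate_relabelings <- function(sample_ids, true_control) {
  if (!all(true_control %in% sample_ids)) {
    stop("true control samples must be a subset of sample_ids")
  }
  n_control <- length(true_control)
  n <- length(sample_ids)
  if (n_control < 1L || n - n_control < 1L) {
    stop("need at least one treated and one control sample")
  }
  ids <- sort(sample_ids)
  combs <- utils::combn(ids, n_control, simplify = FALSE)
  truth <- sort(true_control)
  combs[!vapply(combs, function(x) identical(x, truth), logical(1))]
}

#' DE counts under exhaustive label permutation
#'
#' Reruns the complete per-cell-line DE procedure (detection filter computed
#' once from the data, size factors label-independent, dispersions
#' re-estimated per relabeling, exact test, BH, threshold) for every
#' non-identity relabeling that preserves the group sizes, and summarizes the
#' permutation DE counts against the true-label count. The ratio of
#' permutation to real counts is the empirical false-discovery argument for
#' the real calls.
#'
#' @param dataset A `count_dataset`.
#' @param cell_line Cell line to permute.
#' @param padj_threshold,alpha_floor,min_replicates Passed to [run_de()].
#' @param max_perms Optional cap; when fewer than the full enumeration, a
#'   seeded subsample of relabelings is evaluated.
#' @param seed Seed used only when `max_perms` subsamples.
#' @return A list with `real_de_count`, `perm_de_counts` (one per evaluated
#'   relabeling), `relabelings` (their control sets), `ratio_max` and
#'   `ratio_mean` (NA when the real count is 0), and the real `de` result.
#' @export
permutation_de_counts <- function(dataset, cell_line, padj_threshold = 0.01,
                                  alpha_floor = 1e-8, min_replicates = 3L,
                                  max_perms = Inf, seed = 1L) {
  des <- dataset$design[dataset$design$cell_line == cell_line, , drop = FALSE]
  if (nrow(des) == 0L) stop("unknown cell line: '", cell_line, "'")
  true_control <- des$sample_id[des$condition == "control"]
  relabelings <- enumerate_relabelings(des$sample_id, true_control)
  if (is.finite(max_perms) && max_perms < length(relabelings)) {
    withr::with_seed(seed, {
      relabelings <- relabelings[sort(sample.int(length(relabelings),
                                                 max_perms))]
    })
  }

  real <- run_de(dataset, cell_line, padj_threshold = padj_threshold,
                 alpha_floor = alpha_floor, min_replicates = min_replicates)
  real_n <- length(real$de_genes)

  perm_counts <- vapply(relabelings, function(ctrl) {
    cond <- ifelse(des$sample_id %in% ctrl, "control", "treated")
    de <- run_de(dataset, cell_line, padj_threshold = padj_threshold,
                 alpha_floor = alpha_floor, condition = cond,
                 min_replicates = min_replicates)
    length(de$de_genes)
  }, integer(1))

  list(cell_line = cell_line, real_de_count = real_n,
       perm_de_counts = perm_counts, relabelings = relabelings,
       ratio_max = if (real_n > 0) max(perm_counts) / real_n else NA_real_,
       ratio_mean = if (real_n > 0) mean(perm_counts) / real_n else NA_real_,
       de = real)
}
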