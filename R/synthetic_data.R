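#' Configuration for the negative-binomial count simulator
#'
#' The simulator emulates a multi-cell-line overexpression experiment: each
#' simulated cell line gets `n_treated` treated and `n_control` control
#' replicate libraries of NB-distributed counts with cell-line-specific
#' log-normal baselines, per-sample log-normal library-size factors, and a
#' set of planted treatment-responsive genes partially shared across cell
#' lines with configurable direction concordance.
#'
#' @param n_cell_lines Number of simulated cell lines (default 10, the panel
#'   size the design emulates).
#' @param n_genes Genes per cell line.
#' @param n_treated,n_control Replicate libraries per condition (defaults 6
#'   and 3, the emulated study design).
#' @param baseline_log_mean,baseline_log_sd Natural-log mean and SD of the
#'   per-gene log-normal baseline expression mean.
#' @param dispersion NB over-dispersion `alpha`; the count variance is
#'   `mu + alpha * mu^2`. `0` gives Poisson counts.
#' @param size_factor_log_sd Natural-log SD of the per-sample library-size
#'   factor (log-normal, median 1).
#' @param n_effect_genes Number of planted treatment-responsive genes.
#' @param effect_lfc_magnitude Absolute planted log2 fold change.
#' @param share_prob Probability that a planted gene is re-planted in each
#'   cell line after the first.
#' @param concordance_prob Probability that a re-planted gene keeps the sign
#'   it has in the first cell line.
#' @param seed Integer seed; the same config and seed give bit-identical
#'   output. Each cell line consumes its own RNG stream derived from
#'   `(seed, cell line index)`, so adding cell lines never perturbs earlier
#'   ones.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_cell_lines = 10L, n_genes = 5000L,
                         n_treated = 6L, n_control = 3L,
                         baseline_log_mean = log(100), baseline_log_sd = 1,
                         dispersion = 0.05, size_factor_log_sd = 0.15,
                         n_effect_genes = 300L, effect_lfc_magnitude = 2,
                         share_prob = 0.5, concordance_prob = 0.9,
                         seed = 1L) {
  cfg <- list(n_cell_lines = as.integer(n_cell_lines),
              n_genes = as.integer(n_genes),
              n_treated = as.integer(n_treated),
              n_control = as.integer(n_control),
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              dispersion = dispersion,
              size_factor_log_sd = size_factor_log_sd,
              n_effect_genes = as.integer(n_effect_genes),
              effect_lfc_magnitude = effect_lfc_magnitude,
              share_prob = share_prob, concordance_prob = concordance_prob,
              seed = as.integer(seed))
  with(cfg, {
    if (n_cell_lines < 1L || n_genes < 1L || n_treated < 1L || n_control < 1L)
      stop("cell line, gene and replicate counts must be positive")
    if (n_effect_genes < 0L || n_effect_genes > n_genes)
      stop("n_effect_genes must be in [0, n_genes]")
    if (baseline_log_sd < 0 || dispersion < 0 || size_factor_log_sd < 0)
      stop("baseline_log_sd, dispersion and size_factor_log_sd must be >= 0")
    if (effect_lfc_magnitude <= 0) stop("effect_lfc_magnitude must be > 0")
    for (p in c(share_prob, concordance_prob))
      if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  })
  structure(cfg, class = "synth_config")
}

# Deterministic per-stream seed below 2^31; streams never collide for
# line indices up to 10^5 and base seeds below ~2 * 10^9.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 * 69069 + 104729 * index) %%
               2147483647)
}

nb_draw <- function(n, mu, alpha) {
  if (alpha == 0) stats::rpois(n, lambda = mu)
  else stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate count matrices with planted, partially shared treatment effects
#'
#' For cell line `i`, gene `g`, sample `j` the count is NB with mean
#' `s_j * mu_gi * 2^(lfc_gi * I[j treated])` and dispersion `alpha`, where
#' `mu_gi` is a per-line log-normal baseline and `s_j` a log-normal size
#' factor. Effect genes are chosen once; every effect gene is planted in the
#' first cell line with a random sign, and in each later line independently
#' with probability `share_prob`, keeping the first line's sign with
#' probability `concordance_prob` (flipping it otherwise).
#'
#' @param config A [synth_config()].
#' @return A list with elements `datasets` (named list of `count_dataset`,
#'   one per cell line) and `truth` (data frame with columns `gene_id`,
#'   `cell_line`, `planted_lfc`, `planted_direction`, one row per planting).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  line_ids <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))

  # Global stream: which genes carry effects, and their base sign.
  effect_idx <- integer(0); base_sign <- numeric(0)
  if (cfg$n_effect_genes > 0L) {
    withr::with_seed(derive_seed(cfg$seed, 0L), {
      effect_idx <- sort(sample.int(cfg$n_genes, cfg$n_effect_genes))
      base_sign <- ifelse(stats::runif(cfg$n_effect_genes) < 0.5, 1, -1)
    })
  }

  datasets <- vector("list", cfg$n_cell_lines)
  names(datasets) <- line_ids
  truth <- list()
  n_samp <- cfg$n_treated + cfg$n_control
  treated <- rep(c(TRUE, FALSE), c(cfg$n_treated, cfg$n_control))

  for (i in seq_len(cfg$n_cell_lines)) {
    withr::with_seed(derive_seed(cfg$seed, i), {
      mu <- stats::rlnorm(cfg$n_genes, cfg$baseline_log_mean,
                          cfg$baseline_log_sd)
      s <- stats::rlnorm(n_samp, 0, cfg$size_factor_log_sd)

      lfc <- rep(0, cfg$n_genes)
      if (cfg$n_effect_genes > 0L) {
        if (i == 1L) {
          planted <- rep(TRUE, cfg$n_effect_genes)
          sign_i <- base_sign
        } else {
          planted <- stats::runif(cfg$n_effect_genes) < cfg$share_prob
          keep <- stats::runif(cfg$n_effect_genes) < cfg$concordance_prob
          sign_i <- ifelse(keep, base_sign, -base_sign)
        }
        lfc[effect_idx[planted]] <-
          (sign_i * cfg$effect_lfc_magnitude)[planted]
        if (any(planted)) {
          truth[[i]] <- data.frame(
            gene_id = gene_ids[effect_idx[planted]],
            cell_line = line_ids[i],
            planted_lfc = (sign_i * cfg$effect_lfc_magnitude)[planted],
            planted_direction = ifelse(sign_i[planted] > 0, "up", "down"),
            stringsAsFactors = FALSE)
        }
      }

      mean_mat <- outer(mu, s) * 2^(lfc %o% (treated * 1))
      counts <- matrix(nb_draw(length(mean_mat), as.vector(mean_mat),
                               cfg$dispersion),
                       nrow = cfg$n_genes,
                       dimnames = list(gene_ids, sprintf(
                         "%s_%s%d", line_ids[i],
                         ifelse(treated, "T", "C"),
                         c(seq_len(cfg$n_treated), seq_len(cfg$n_control)))))
      design <- data.frame(
        sample_id = colnames(counts),
        cell_line = line_ids[i],
        condition = ifelse(treated, "treated", "control"),
        replicate = c(seq_len(cfg$n_treated), seq_len(cfg$n_control)),
        stringsAsFactors = FALSE)
      datasets[[i]] <- new_count_dataset(counts, design)
    })
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(0), cell_line = character(0),
               planted_lfc = numeric(0), planted_direction = character(0),
               stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(datasets = datasets, truth = truth)
}

#' Planted direction indicators as a gene-by-cell-line matrix
#'
#' @param truth Truth table from [generate_counts()].
#' @return Numeric matrix, genes in rows, cell lines in columns; `1` for an
#'   up-planting, `0` for a down-planting, `NA` where nothing was planted.
#' @export
truth_direction_matrix <- function(truth) {
  genes <- sort(unique(truth$gene_id))
  lines <- sort(unique(truth$cell_line))
  m <- matrix(NA_real_, length(genes), length(lines),
              dimnames = list(genes, lines))
  if (nrow(truth)) {
    m[cbind(match(truth$gene_id, genes), match(truth$cell_line, lines))] <-
      as.numeric(truth$planted_lfc > 0)
  }
  m
}
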