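#' Expression-detection filter for one cell line
#'
#' A gene counts as expressed in a cell line if at least one read was
#' assigned to it in at least three of that cell line's replicate libraries,
#' treated and control pooled (the filter does not reference the labels).
#'
#' @param dataset A `count_dataset`.
#' @param cell_line Cell line to filter for.
#' @param min_replicates Minimum number of libraries with a nonzero count
#'   (default 3).
#' @return Character vector of expressed gene ids.
#' @export
detect_expressed <- function(dataset, cell_line, min_replicates = 3L) {
  samples <- dataset$design$sample_id[dataset$design$cell_line == cell_line]
  if (length(samples) == 0L) stop("unknown cell line: '", cell_line, "'")
  sub <- dataset$counts[, samples, drop = FALSE]
  rownames(sub)[rowSums(sub >= 1L) >= min_replicates]
}

#' Median-of-ratios library-size factors
#'
#' For sample `j`, the factor is the median over genes of
#' `count[g, j] / geomean_g`, where `geomean_g` is the geometric mean of gene
#' `g` across all samples; genes with a zero count in any sample are excluded
#' (their geometric mean is zero).
#'
#' @param counts Count matrix (genes x samples) or a `count_dataset`.
#' @return Named numeric vector of strictly positive size factors.
#' @export
estimate_size_factors <- function(counts) {
  if (inherits(counts, "count_dataset")) counts <- counts$counts
  logc <- log(counts)
  log_geo <- rowMeans(logc)
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    stop("no gene has a nonzero count in every sample; ",
         "median-of-ratios is undefined (pseudo-reference fallback disabled)")
  }
  ratios <- exp(sweep(logc[usable, , drop = FALSE], 1L, log_geo[usable]))
  sf <- apply(ratios, 2L, stats::median)
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factor estimated")
  sf
}

#' NB dispersion estimates for one cell line
#'
#' On size-factor-normalized counts `q = k / s`, with `m` the mean over all
#' of the cell line's samples, `v` the pooled (df-weighted) within-condition
#' variance, and `z = m * mean(1/s)` the shot-noise term, the per-gene
#' method-of-moments dispersion is `alpha = max(alpha_floor, (v - z) / m^2)`.
#' Genes with zero mean get `alpha_floor`.
#'
#' With only a handful of replicates the per-gene moments estimate is noisy,
#' and genes whose dispersion is understated by chance produce spuriously
#' small exact-test p-values. `method = "trend"` therefore replaces `v` by a
#' robust local-regression fit of `log v` on `log m` across genes (the
#' strategy of the early NB-test packages this procedure follows), and the
#' default `method = "max"` takes the elementwise maximum of the per-gene
#' and trend estimates — conservative by construction. `"per_gene"` gives
#' the raw moments estimate. When fewer than `min_trend_genes` genes are
#' usable for the fit, the per-gene estimate is returned.
#'
#' @param dataset A `count_dataset`.
#' @param factors Size factors for (at least) the cell line's samples.
#' @param cell_line Cell line to estimate for.
#' @param alpha_floor Lower bound for the dispersion (default `1e-8`).
#' @param condition Optional condition labels overriding the design (used by
#'   the permutation machinery); in the order of the cell line's samples.
#' @param method One of `"max"` (default), `"per_gene"`, `"trend"`.
#' @param min_trend_genes Minimum usable genes for the trend fit (default
#'   50).
#' @return Named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(dataset, factors, cell_line,
                                alpha_floor = 1e-8, condition = NULL,
                                method = c("max", "per_gene", "trend"),
                                min_trend_genes = 50L) {
  method <- match.arg(method)
  des <- dataset$design[dataset$design$cell_line == cell_line, , drop = FALSE]
  if (nrow(des) == 0L) stop("unknown cell line: '", cell_line, "'")
  cond <- if (is.null(condition)) as.character(des$condition) else
    as.character(condition)
  if (length(cond) != nrow(des)) stop("condition labels do not match samples")
  if (any(table(cond) < 2L) || length(unique(cond)) != 2L) {
    stop("dispersion estimation needs >= 2 replicates in each of two conditions")
  }
  k <- dataset$counts[, des$sample_id, drop = FALSE]
  s <- factors[des$sample_id]
  if (any(is.na(s))) stop("missing size factor for some sample")
  q <- sweep(k, 2L, s, "/")

  m <- rowMeans(q)
  groups <- split(seq_along(cond), cond)
  ss <- 0; df <- 0
  for (idx in groups) {
    qg <- q[, idx, drop = FALSE]
    ss <- ss + rowSums((qg - rowMeans(qg))^2)
    df <- df + length(idx) - 1L
  }
  v <- ss / df
  z <- m * mean(1 / s)
  per_gene <- ifelse(m > 0, pmax(alpha_floor, (v - z) / m^2), alpha_floor)

  alpha <- per_gene
  if (method != "per_gene") {
    ok <- m > 0 & v > 0
    if (sum(ok) >= min_trend_genes) {
      lo <- stats::lowess(log(m[ok]), log(v[ok]), f = 0.2)
      vfit <- exp(stats::approx(lo$x, lo$y, xout = log(pmax(m, min(m[ok]))),
                                rule = 2, ties = mean)$y)
      trend <- ifelse(m > 0, pmax(alpha_floor, (vfit - z) / m^2),
                      alpha_floor)
      alpha <- if (method == "trend") trend else pmax(per_gene, trend)
    }
  }
  names(alpha) <- rownames(k)
  alpha
}

# Log-density of the NB model used for a group total: mean mu and variance
# var >= mu (var == mu degenerates to Poisson).
lognb_total <- function(x, mu, var) {
  if (mu == 0) return(ifelse(x == 0, 0, -Inf))
  if (var <= mu * (1 + 1e-12)) return(stats::dpois(x, lambda = mu, log = TRUE))
  size <- mu^2 / (var - mu)
  stats::dnbinom(x, mu = mu, size = size, log = TRUE)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Conditional NB exact test on two group count totals
#'
#' With `K_A`, `K_B` the raw count sums of the two groups and
#' `K = K_A + K_B`, the group totals are modeled as NB variables whose mean
#' is the common normalized mean scaled by the group's total size factor and
#' whose variance is the sum of the per-sample NB variances under the common
#' dispersion. The two-sided p-value is the conditional probability, given
#' `K`, of any split `(a, b)` no more likely than the observed one:
#' `p = sum over {a + b = K : Pr(a,b) <= Pr(K_A,K_B)} Pr(a,b) /
#'      sum over {a + b = K} Pr(a,b)`.
#' All mass is computed in log space and the conditional sum is normalized by
#' the enumerated denominator.
#'
#' @param k Integer vector of one gene's counts.
#' @param group Logical or two-level vector splitting `k` into groups A/B.
#' @param factors Size factors aligned with `k`.
#' @param alpha Common NB dispersion (>= 0).
#' @return Two-sided p-value in `(0, 1]`.
#' @export
nb_exact_test <- function(k, group, factors, alpha) {
  if (any(k < 0)) stop("negative counts")
  if (alpha < 0) stop("alpha must be >= 0")
  grp <- as.factor(group)
  if (nlevels(grp) != 2L || any(tabulate(grp, 2L) == 0L)) {
    stop("need two non-empty groups")
  }
  in_a <- as.integer(grp) == 1L
  kA <- sum(k[in_a]); kB <- sum(k[!in_a]); K <- kA + kB
  if (K == 0L) return(1)
  sA <- factors[in_a]; sB <- factors[!in_a]
  qhat <- K / sum(factors)
  muA <- qhat * sum(sA); muB <- qhat * sum(sB)
  varA <- sum(sA * qhat + alpha * (sA * qhat)^2)
  varB <- sum(sB * qhat + alpha * (sB * qhat)^2)

  a <- 0:K
  logp <- lognb_total(a, muA, varA) + lognb_total(K - a, muB, varB)
  obs <- logp[kA + 1L]
  denom <- logsumexp(logp)
  keep <- logp <= obs + 1e-12
  p <- exp(logsumexp(logp[keep]) - denom)
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values (monotone step-up, capped at 1), in input order.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  padj <- pmin(1, cummin(n / (n:1) * p[o]))
  padj[order(o)]
}

#' Differential expression for one cell line
#'
#' Runs the full per-cell-line procedure: expression-detection filter, size
#' factors (median-of-ratios over the cell line's samples), per-gene
#' method-of-moments dispersion, the conditional NB exact test per expressed
#' gene, and Benjamini-Hochberg adjustment across that cell line's tested
#' genes. A gene is called differentially expressed when its adjusted p-value
#' is below `padj_threshold`.
#'
#' @param dataset A `count_dataset`.
#' @param cell_line Cell line to analyse.
#' @param padj_threshold Adjusted-p cutoff for the DE call (default 0.01).
#' @param alpha_floor Dispersion floor, see [estimate_dispersion()].
#' @param condition Optional condition relabeling (see
#'   [estimate_dispersion()]); the detection filter and size factors do not
#'   depend on it.
#' @param min_replicates Detection-filter threshold, see [detect_expressed()].
#' @param dispersion_method Dispersion estimator variant, see
#'   [estimate_dispersion()].
#' @return A list with `results` (data frame: `gene_id`, `mean_treated`,
#'   `mean_control` (normalized), `log2_fold_change`, `p_raw`, `p_adj`,
#'   `direction` with 1 = higher after treatment, 0 = lower, NA = equal) and
#'   `de_genes` (character vector of DE gene ids), plus the `size_factors`
#'   and `dispersions` used.
#' @export
run_de <- function(dataset, cell_line, padj_threshold = 0.01,
                   alpha_floor = 1e-8, condition = NULL,
                   min_replicates = 3L,
                   dispersion_method = c("max", "per_gene", "trend")) {
  dispersion_method <- match.arg(dispersion_method)
  des <- dataset$design[dataset$design$cell_line == cell_line, , drop = FALSE]
  if (nrow(des) == 0L) stop("unknown cell line: '", cell_line, "'")
  cond <- if (is.null(condition)) as.character(des$condition) else
    as.character(condition)
  if (any(table(cond) < 2L)) {
    stop("run_de needs >= 2 replicates per condition")
  }

  expressed <- detect_expressed(dataset, cell_line,
                                min_replicates = min_replicates)
  k_all <- dataset$counts[, des$sample_id, drop = FALSE]
  sf <- estimate_size_factors(k_all)
  alpha <- estimate_dispersion(dataset, sf, cell_line,
                               alpha_floor = alpha_floor, condition = cond,
                               method = dispersion_method)

  k <- k_all[expressed, , drop = FALSE]
  treated <- cond == "treated"
  q <- sweep(k, 2L, sf, "/")
  mean_t <- rowMeans(q[, treated, drop = FALSE])
  mean_c <- rowMeans(q[, !treated, drop = FALSE])

  grp <- factor(ifelse(treated, "A", "B"), c("A", "B"))
  p_raw <- vapply(seq_along(expressed), function(i) {
    nb_exact_test(k[i, ], grp, sf, alpha[[expressed[i]]])
  }, numeric(1))
  p_adj <- adjust_bh(p_raw)

  lfc <- ifelse(mean_t > 0 & mean_c > 0, log2(mean_t / mean_c), NA_real_)
  direction <- ifelse(mean_t > mean_c, 1L,
                      ifelse(mean_t < mean_c, 0L, NA_integer_))
  results <- data.frame(gene_id = expressed, mean_treated = mean_t,
                        mean_control = mean_c, log2_fold_change = lfc,
                        p_raw = p_raw, p_adj = p_adj, direction = direction,
                        stringsAsFactors = FALSE, row.names = NULL)
  list(cell_line = cell_line, results = results,
       de_genes = results$gene_id[results$p_adj < padj_threshold],
       expressed = expressed, size_factors = sf, dispersions = alpha,
       padj_threshold = padj_threshold)
}
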