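# Builders for small in-memory fixtures.

# A count_dataset for one cell line from a bare matrix; columns are split
# into the first `n_treated` treated and the rest control samples.
make_dataset <- function(counts, n_treated, cell_line = "CL01") {
  n <- ncol(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  }
  colnames(counts) <- sprintf("%s_s%d", cell_line, seq_len(n))
  cond <- rep(c("treated", "control"), c(n_treated, n - n_treated))
  design <- data.frame(
    sample_id = colnames(counts), cell_line = cell_line, condition = cond,
    replicate = c(seq_len(n_treated), seq_len(n - n_treated)),
    stringsAsFactors = FALSE)
  new_count_dataset(counts, design)
}

# A fake run_de() result with just the fields downstream summaries consume.
make_de_result <- function(cell_line, gene_ids, directions, de_genes,
                           expressed = gene_ids) {
  list(cell_line = cell_line,
       results = data.frame(gene_id = gene_ids, direction = directions,
                            stringsAsFactors = FALSE),
       de_genes = de_genes, expressed = expressed)
}

# Independent linear-space oracle for the conditional NB exact test: direct
# products of dnbinom masses, no log-space accumulation. Mirrors the stated
# model: group-total means from the pooled normalized mean, variances as
# sums of per-sample NB variances.
oracle_exact_p <- function(k, in_a, factors, alpha) {
  kA <- sum(k[in_a]); kB <- sum(k[!in_a]); K <- kA + kB
  if (K == 0) return(1)
  qhat <- K / sum(factors)
  mass <- function(x, s_grp) {
    mu <- qhat * sum(s_grp)
    v <- sum(s_grp * qhat + alpha * (s_grp * qhat)^2)
    if (v <= mu * (1 + 1e-12)) dpois(x, mu)
    else dnbinom(x, mu = mu, size = mu^2 / (v - mu))
  }
  a <- 0:K
  ps <- mass(a, factors[in_a]) * mass(K - a, factors[!in_a])
  pobs <- ps[kA + 1]
  sum(ps[ps <= pobs * (1 + 1e-9)]) / sum(ps)
}

# Monte-Carlo standard error of a mean.
mc_se <- function(x) sd(x) / sqrt(length(x))
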