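---
title: "Methods: models, nulls and design choices in crossde"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, nulls and design choices in crossde}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossde)
```

## Scope and data model

`crossde` analyses a panel experiment: the same treatment applied to several
cell lines, each sequenced as a few treated and a few mock-treated replicate
RNA-seq libraries, summarised as gene-by-sample integer count matrices.
The package starts from counts; alignment and read counting are upstream
concerns. Gene identifiers are opaque strings — no validation or conversion
is attempted.

A `count_dataset` couples the integer matrix with a design table
(`sample_id`, `cell_line`, `condition` ∈ {treated, control}, `replicate`);
validation enforces integer non-negative counts, unique ids, and an exact
match between matrix and design sample sets.

## Per-cell-line differential expression

**Detection filter.** A gene is *expressed* in a cell line if it has at
least one read in at least three of that line's libraries, treated and
control pooled. The pooled reading is a deliberate choice: the filter is a
statement about detectability, not about the contrast, so it must not
reference the labels — this also lets the permutation stage reuse one
filter for every relabeling.

**Normalization.** Median-of-ratios size factors: for sample $j$,
$s_j = \mathrm{median}_g\, k_{gj} / (\prod_v k_{gv})^{1/n}$ over genes with
no zero count. The median is taken on the ratio scale (for an even number
of usable genes this is the arithmetic mean of the two central ratios).
There is no pseudo-reference fallback: if no gene is free of zeros the
estimator stops with an error rather than silently switching models.

**Dispersion.** Counts are NB with $V(\mu) = \mu + \alpha\mu^2$. Writing
$q_{gj} = k_{gj}/s_j$, $m_g$ for the mean of $q_g$ over the line's samples,
$v_g$ for the df-weighted pooled within-condition variance and
$z_g = m_g \cdot \overline{1/s}$ for the shot-noise term, the per-gene
moments estimate is
$\hat\alpha_g = \max(\alpha_{\min}, (v_g - z_g)/m_g^2)$ with
$\alpha_{\min} = 10^{-8}$.

With only $6+3$ replicates this estimate is very noisy, and noise is not
symmetric in its consequences: a gene whose dispersion is *under*-estimated
by chance is tested as nearly Poisson and produces a spuriously small
p-value. Measured on 5,000-gene null simulations at $\alpha = 0.05$, pure
per-gene moments gave a raw-p $< 0.01$ fraction of ≈ 0.035 — an inflated
type-I error. The default estimator (`method = "max"`) therefore also fits
a robust lowess trend of $\log v$ on $\log m$ across genes and takes the
element-wise **maximum** of the per-gene and trend-implied dispersions —
the conservative sharing strategy of the early NB-exact-test packages this
procedure follows. With it, the same null simulations give a raw-p
$< 0.01$ fraction of ≈ 0.009–0.010 and zero BH discoveries at the 1%
threshold. The pure per-gene estimator remains available
(`method = "per_gene"`) and is what the unit tests check against the
hand-computed formula; the trend fit falls back to per-gene moments when
fewer than 50 genes are usable, so tiny fixtures are unaffected.

**Exact test.** Group totals $K_A, K_B$ are modeled as NB variables: mean
$\hat q \sum_{j \in A} s_j$ with $\hat q = K/\sum_j s_j$, variance
$\sum_{j \in A} (s_j\hat q + \alpha (s_j\hat q)^2)$ (likewise for $B$),
each converted to an NB size parameter $\mu^2/(V-\mu)$, degenerating to
Poisson when $V \le \mu$. Conditioning on $K = K_A + K_B$, the two-sided
p-value sums the probabilities of all splits no more likely than the
observed one, normalized by the enumerated denominator:

$$p = \frac{\sum_{a+b=K,\ \Pr(a,b)\le\Pr(K_A,K_B)} \Pr(a,b)}
           {\sum_{a+b=K} \Pr(a,b)}.$$

All mass is computed in log space; the tie rule includes terms within a
$10^{-12}$ log-tolerance of the observed mass so that symmetric ties are
kept regardless of rounding order; $p$ is clamped to $(0,1]$. The choice
of the probability-ordering two-sided rule (rather than tail doubling)
matches the convention of the conditional NB test family. An exhaustive
linear-space enumeration oracle in the test suite confirms agreement to
$10^{-10}$ for $K \le 60$.

**Multiplicity.** Benjamini–Hochberg step-up within each cell line's tested
genes — the analysis is per line, so the family is per line. DE call at
`p_adj < 0.01`. Fold change is reported as `log2(mean_T / mean_C)` on
normalized means and flagged `NA` when either mean is zero; the direction
indicator (1 = higher after treatment, 0 = lower, NA = equal) uses the raw
normalized means without any pseudocount.

## Exhaustive label permutation

For the 6-vs-3 design there are $\binom{9}{3} = 84$ label assignments; the
83 non-identity ones are enumerated (lexicographically over sorted sample
ids) and the *complete* procedure — dispersion estimation included, since
labels enter it — is re-run for each. The detection filter and size
factors are label-independent and computed once. The summary compares the
largest and mean permutation DE counts with the true-label count; ratios
are `NA` when the real count is zero. A seeded subsampling cap
(`max_perms`) exists for larger designs, unused at the native scale.

## Cross-line concordance

**Overlap null.** For a pair of lines with DE sets of sizes $n_a, n_b$,
each draw independently samples $n_a$ genes from line A's expressed genes
and $n_b$ from line B's (each line's own universe — the literal design),
recording the intersection size; the observed overlap is standardized into
$z = (\mathrm{obs} - \bar x)/\mathrm{sd}$. The SD uses the population
denominator (`n_draws`): the z-score is a descriptive standardization, not
an inference, so no small-sample correction is warranted. The null mean
has the closed form $|U_a \cap U_b| \frac{n_a}{|U_a|}\frac{n_b}{|U_b|}$,
which the tests verify to Monte-Carlo accuracy. Pairs with an empty DE set
report `z = NA` rather than being dropped.

**Direction summaries.** Per line, the mean of the 1/0 indicator over all
tested genes with a defined direction, over genes DE in ≥ 1 line, and over
strata of genes DE in exactly $k$ lines. Under a null treatment the
all-genes mean concentrates near 0.5; genuinely shared responses drag the
high-$k$ strata toward 0 or 1. Directions are computed for *all* tested
genes, not only DE ones, because the all-genes average requires them.

**External-list overlap.** The foreground (by default genes DE in ≥ 2
lines) is intersected with an external reference list; random foregrounds
of the same size are drawn from the genes expressed in ≥ 2 lines, and the
empirical p is the fraction of draws with overlap **≥** the observed one.
The `≥` rule is the conservative reading of "this extent of overlap";
`strict = TRUE` switches to `>`. With `n_draws` → ∞ this converges to the
hypergeometric upper tail, which the tests check at 3 Monte-Carlo SEs.

## Category enrichment

Annotations are consumed pre-propagated (each category's gene set already
includes descendants); gene sets are intersected with the analysis universe
before anything else, so unexpressed genes neither help nor dilute a
category. Per category, the upper-tail hypergeometric p. Significance
requires `p < 0.1` *and* a permutation family-wise error criterion:
`n_perms` random foregrounds of the observed size yield a null
distribution of the *minimum* category p (the min-p / step-down idea), and
a category passes when the fraction of null minima at or below its p is
under 0.1. The permutation route was chosen because an analytic FWER for
overlapping categories has no clean closed form; min-p handles the
dependence automatically.

Pruning applies two rules: categories with fewer than 5 universe genes are
dropped (`too_small`); then, scanning significant categories in ascending-p
order (ties broken lexicographically by id, "lower p" read strictly), a
category is dropped as `redundant` when more than 90% of its universe genes
already lie in the union of *retained* significant categories with strictly
lower p. Pruned categories never enter that union and are never reported
significant; the output is invariant to input order.

## The synthetic world

`generate_counts()` emulates the panel design: per cell line, `n_treated =
6` and `n_control = 3` libraries; per-gene baselines
$\mu_g \sim \mathrm{LogNormal}(\log 100,\ 1)$ drawn independently per line
(cell-line-specific baselines); library-size factors
$s_j \sim \mathrm{LogNormal}(0, 0.15)$; counts
$\mathrm{NB}(s_j \mu_g 2^{\mathrm{lfc}\cdot I[j\ \mathrm{treated}]},\
\alpha)$ with $\alpha = 0.05$ by default. Defaults were chosen once as
typical of moderately deep bulk libraries — median gene mean ≈ 100 with a
1-log-SD spread gives the two-to-three-decade dynamic range of detected
genes, ±15% library-size variation is routine, and $\alpha = 0.05$ is a
mid-range biological CV of ≈ 22% — and are not tuned against any test
outcome. Effects: `n_effect_genes = 300` genes chosen once from a global
stream, each planted in the first line with a random sign and magnitude
`effect_lfc_magnitude = 2` (log2), re-planted in each later line with
probability `share_prob` keeping its sign with probability
`concordance_prob`; effects multiply treated means only. Each cell line
consumes an RNG stream derived from `(seed, line index)`, so extending the
panel never changes earlier lines, and the same config and seed are
bit-identical.

What the simulator does **not** emulate: gene length and GC effects,
lane/batch structure, correlated gene modules, outlier replicates, or
isoform-level variation. A green test therefore establishes that the
machinery is correct and calibrated under an honest NB world with planted
effects — not that any particular biological dataset satisfies the NB
assumptions.

## Numerical and degenerate-input contracts

* NB mass in log space throughout; conditional sums normalized by the
  enumerated denominator; p clamped to `(0, 1]`.
* All-zero gene or both groups all zero → p = 1; zero-mean gene →
  dispersion floor; a mean of zero makes the fold change `NA` (no
  pseudocount is injected into the test statistics; the QC correlation is
  the one place a `+1` pseudocount appears, on log-transformed normalized
  counts, where monotonicity makes the rank correlation insensitive to it).
* Resampling utilities (`overlap_null`, `list_overlap_empirical_p`,
  `fwer_adjust`, the simulator) take explicit seeds and are bit-reproducible
  given `(seed, n_draws)`; nothing reads or perturbs the caller's RNG state
  (`withr::with_seed`).
* BH is implemented directly (step-up with cumulative minima) and verified
  against `stats::p.adjust`'s reference in the tests.

## Known limitations

* The exact test enumerates all $K+1$ splits of a gene's total count; cost
  is linear in total counts. Fine at bulk scale (a 5,000-gene, 9-library
  line takes ≈ 2 s per full DE pass), but very deep libraries would warrant
  a compiled kernel or a tail-splitting enumeration.
* Dispersion sharing by `max` is deliberately conservative; it costs some
  power for genes that are genuinely quieter than the trend.
* The permutation FDR argument assumes exchangeability of libraries within
  a line; confounded batch structure would violate it silently.
* Empirical p-values are bounded below by `1 / n_draws`; they are reported
  as fractions, not corrected by the `(r+1)/(n+1)` rule, matching the
  plain "fraction of random sets" definition used throughout.
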