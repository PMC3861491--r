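Package: crossde
Title: Cross-Cell-Line Differential Expression with Permutation False
    Discovery Control and Concordance Analysis
Version: 0.1.0
Authors@R:
    person("crossde", "maintainers", email = "crossde@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing treatment-versus-control RNA-seq count
    matrices across a panel of cell lines. Implements median-of-ratios
    library-size normalisation, per-gene method-of-moments dispersion
    estimation, the two-sided conditional negative-binomial exact test on
    group count totals, Benjamini-Hochberg adjustment, exhaustive
    treated/control label-permutation false-discovery assessment,
    cross-cell-line overlap statistics against resampling nulls,
    direction-of-change concordance summaries, external gene-list overlap
    empirical p-values, and hypergeometric category enrichment with
    family-wise error control and redundancy pruning. A negative-binomial
    count simulator with planted, partially shared treatment effects
    supports end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
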