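test_that("detection filter requires a read in at least three libraries", {
  m <- rbind(g1 = c(1, 1, 1, 0, 0, 0, 0, 0, 0),
             g2 = c(50, 0, 0, 0, 0, 0, 0, 0, 0),
             g3 = rep(0, 9),
             g4 = rep(2, 9))
  ds <- make_dataset(m, n_treated = 6)
  expect_identical(detect_expressed(ds, "CL01"), c("g1", "g4"))
  expect_error(detect_expressed(ds, "CL99"), "unknown cell line")
})

test_that("median-of-ratios size factors match closed forms and brute force", {
  m <- matrix(rep(c(3L, 8L, 20L), 3), ncol = 3,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b", "c")))
  expect_equal(estimate_size_factors(m), c(a = 1, b = 1, c = 1))

  two <- cbind(a = c(4L, 10L, 7L), b = c(8L, 20L, 14L))
  rownames(two) <- c("g1", "g2", "g3")
  expect_equal(estimate_size_factors(two),
               c(a = 1 / sqrt(2), b = sqrt(2)))

  # brute-force evaluation of the defining formula on random small integers
  set.seed(101)
  k <- matrix(rpois(15, 20) + 1L, 5, 3,
              dimnames = list(sprintf("g%d", 1:5), c("a", "b", "c")))
  geo <- apply(k, 1, function(x) prod(x)^(1 / 3))
  manual <- apply(k, 2, function(col) median(col / geo))
  expect_equal(estimate_size_factors(k), manual, tolerance = 1e-12)

  # genes with zeros are excluded from the median
  kz <- k; kz[2, 1] <- 0L
  geo_z <- apply(kz[-2, ], 1, function(x) prod(x)^(1 / 3))
  manual_z <- apply(kz[-2, ], 2, function(col) median(col / geo_z))
  expect_equal(estimate_size_factors(kz), manual_z, tolerance = 1e-12)

  all_zero_somewhere <- rbind(g1 = c(0L, 3L), g2 = c(4L, 0L))
  colnames(all_zero_somewhere) <- c("a", "b")
  expect_error(estimate_size_factors(all_zero_somewhere), "median-of-ratios")
})

test_that("size factors are scale-equivariant", {
  set.seed(7)
  k <- matrix(rpois(40, 30) + 1L, 10, 4,
              dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:4)))
  base <- estimate_size_factors(k)
  for (c_mult in c(2L, 5L)) {
    k2 <- k; k2[, 2] <- k[, 2] * c_mult
    scaled <- estimate_size_factors(k2)
    # multiplying one sample scales its factor by c and every factor by the
    # common geometric-mean shift c^(-1/n)
    shift <- c_mult^(-1 / ncol(k))
    expect_equal(scaled[2], base[2] * c_mult * shift, tolerance = 1e-12)
    expect_equal(scaled[-2], base[-2] * shift, tolerance = 1e-12)
  }
})

test_that("per-gene moments dispersion matches a hand computation", {
  m <- rbind(g1 = c(10, 30, 20, 5, 9, 7),
             g2 = c(4, 4, 4, 4, 4, 4),
             g3 = rep(0, 6))
  ds <- make_dataset(m, n_treated = 3)
  sf <- setNames(rep(1, 6), colnames(ds$counts))
  a <- estimate_dispersion(ds, sf, "CL01", method = "per_gene")

  q1 <- m["g1", ]
  mm <- mean(q1)
  v <- (sum((q1[1:3] - mean(q1[1:3]))^2) +
          sum((q1[4:6] - mean(q1[4:6]))^2)) / 4
  expect_equal(a[["g1"]], max(1e-8, (v - mm) / mm^2), tolerance = 1e-12)

  expect_identical(a[["g2"]], 1e-8)  # zero variance -> floored
  expect_identical(a[["g3"]], 1e-8)  # zero mean -> floored

  expect_error(estimate_dispersion(ds, sf, "CL01",
                                   condition = rep("treated", 6)),
               ">= 2 replicates")
})

test_that("conservative default dispersion dominates the per-gene one", {
  sim <- generate_counts(synth_config(n_cell_lines = 1, n_genes = 400,
                                      n_effect_genes = 0, seed = 21))
  ds <- sim$datasets[[1]]
  sf <- estimate_size_factors(ds$counts)
  pg <- estimate_dispersion(ds, sf, "CL01", method = "per_gene")
  mx <- estimate_dispersion(ds, sf, "CL01", method = "max")
  expect_true(all(mx >= pg - 1e-15))
})

test_that("exact test handles degenerate and symmetric inputs", {
  sf <- rep(1, 6)
  grp <- rep(c("A", "B"), each = 3)
  expect_identical(nb_exact_test(rep(0L, 6), grp, sf, 0.1), 1)

  k <- c(9L, 14L, 11L, 2L, 5L, 3L)
  p_ab <- nb_exact_test(k, grp, sf, 0.07)
  p_ba <- nb_exact_test(k, rev(grp), rev(sf), 0.07)
  expect_equal(p_ab, p_ba, tolerance = 1e-12)

  expect_error(nb_exact_test(c(-1L, 2L), c("A", "B"), c(1, 1), 0.1),
               "negative")
  expect_error(nb_exact_test(c(1L, 2L), c("A", "A"), c(1, 1), 0.1),
               "two non-empty groups")
})

test_that("exact test equals exhaustive enumeration", {
  # the spec'd small case: K = 6 split 5|1, equal groups, unit factors
  k <- c(3L, 2L, 0L, 1L)
  grp <- c("A", "A", "B", "B")
  sf <- rep(1, 4)
  expect_equal(nb_exact_test(k, grp, sf, 0.1),
               oracle_exact_p(k, grp == "A", sf, 0.1), tolerance = 1e-10)

  # randomized instances across group sizes, factors and dispersions
  set.seed(202)
  for (i in 1:60) {
    nA <- sample(2:4, 1); nB <- sample(2:4, 1)
    sf <- round(exp(rnorm(nA + nB, 0, 0.2)), 3)
    alpha <- sample(c(0, 0.01, 0.1, 0.6), 1)
    repeat {
      k <- rpois(nA + nB, sample(c(1, 4, 8), 1))
      if (sum(k) <= 60) break
    }
    in_a <- rep(c(TRUE, FALSE), c(nA, nB))
    got <- nb_exact_test(k, ifelse(in_a, "A", "B"), sf, alpha)
    want <- oracle_exact_p(k, in_a, sf, alpha)
    expect_equal(got, want, tolerance = 1e-10,
                 label = sprintf("case %d (k=%s, alpha=%g)", i,
                                 paste(k, collapse = ","), alpha))
  }
})

test_that("BH adjustment matches the step-up formula and reference", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_bh(0.4), 0.4)
  expect_error(adjust_bh(c(0.5, 0)), "p-values")
  expect_error(adjust_bh(c(0.5, 1.2)), "p-values")

  set.seed(303)
  for (i in 1:20) {
    p <- round(runif(sample(1:12, 1)), 2)
    p[p == 0] <- 0.01
    if (i %% 3 == 0) p[1:2] <- p[1]  # force ties
    expect_equal(adjust_bh(p), p.adjust(p, "BH"), tolerance = 1e-12)

    perm <- sample(length(p))
    expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(adjust_bh(p)[o]) >= -1e-12))
  }
})

test_that("run_de filters, calls overwhelming effects, and reports direction", {
  sim <- generate_counts(synth_config(
    n_cell_lines = 1, n_genes = 200, n_effect_genes = 5,
    baseline_log_mean = log(500), baseline_log_sd = 0,
    effect_lfc_magnitude = 4, dispersion = 0.05, seed = 31))
  ds <- sim$datasets[[1]]
  # make one non-effect gene unexpressed: nonzero in only two libraries
  null_gene <- setdiff(rownames(ds$counts), sim$truth$gene_id)[1]
  ds$counts[null_gene, ] <- c(3L, 1L, rep(0L, 7))

  de <- run_de(ds, "CL01")
  expect_false(null_gene %in% de$results$gene_id)
  expect_true(all(sim$truth$gene_id %in% de$de_genes))

  up <- sim$truth$gene_id[sim$truth$planted_lfc > 0]
  down <- sim$truth$gene_id[sim$truth$planted_lfc < 0]
  res <- de$results
  expect_true(all(res$direction[match(up, res$gene_id)] == 1L))
  expect_true(all(res$direction[match(down, res$gene_id)] == 0L))
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  expect_true(all(res$p_raw > 0 & res$p_raw <= 1))

  # log2 fold change consistent with normalized means
  i <- match(up[1], res$gene_id)
  expect_equal(res$log2_fold_change[i],
               log2(res$mean_treated[i] / res$mean_control[i]))
})
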