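test_that("hypergeometric p matches closed forms", {
  expect_equal(hypergeom_p(10, 10, 5, 5), 1)
  expect_equal(hypergeom_p(10, 4, 5, 0), 1)
  expect_equal(hypergeom_p(10, 4, 5, 4), 6 / 252)  # C(4,4)C(6,1)/C(10,5)
  expect_error(hypergeom_p(10, 4, 5, 5), "inconsistent")
})

test_that("hypergeometric p equals exhaustive enumeration (universe <= 15)", {
  set.seed(404)
  for (i in 1:15) {
    n_u <- sample(6:12, 1)
    n_c <- sample(1:n_u, 1)
    n_f <- sample(1:n_u, 1)
    universe <- seq_len(n_u)
    category <- seq_len(n_c)
    # enumerate every foreground of size n_f and count overlaps >= observed
    combs <- combn(n_u, n_f)
    overlaps <- colSums(matrix(combs %in% category, nrow = n_f))
    obs <- sample(0:min(n_c, n_f), 1)
    expect_equal(hypergeom_p(n_u, n_c, n_f, obs),
                 mean(overlaps >= obs), tolerance = 1e-12,
                 label = sprintf("u=%d c=%d f=%d o=%d", n_u, n_c, n_f, obs))
  }
})

test_that("min-p permutation FWER criterion behaves at the extremes", {
  universe <- sprintf("g%d", 1:40)
  ann <- list(cat1 = universe[1:10], cat2 = universe[11:25])
  fg <- universe[c(1:6, 30:31)]

  p <- c(cat1 = hypergeom_p(40, 10, 8, 6), cat2 = 1)
  fw <- fwer_adjust(p, ann, fg, universe, n_perms = 400, seed = 5)
  expect_identical(fw$category_id, c("cat1", "cat2"))
  # a category with p = 1 never meets the criterion: every min-p <= 1
  expect_identical(fw$fwer[fw$category_id == "cat2"], 1)
  expect_false(fw$fwer_ok[fw$category_id == "cat2"])
  # a very small p sits below the 0.1 quantile of the min-p null
  expect_true(fw$fwer_ok[fw$category_id == "cat1"])

  expect_error(fwer_adjust(p, ann, universe, universe[1:5]),
               "larger than universe")
})

test_that("permutation FWER controls the family-wise error on null data", {
  universe <- sprintf("g%d", 1:60)
  ann <- list(c1 = universe[1:15], c2 = universe[31:45])  # independent-ish
  n_seeds <- 50
  any_fp <- withr::with_seed(606, {
    vapply(seq_len(n_seeds), function(s) {
      fg <- sample(universe, 12)
      res <- run_enrichment(fg, universe, ann, n_perms = 400,
                            seed = 10000 + s)
      any(res$significant)
    }, logical(1))
  })
  rate <- mean(any_fp)
  expect_lte(rate, 0.1 + 3 * sqrt(0.1 * 0.9 / n_seeds))
})

test_that("pruning applies the size and redundancy rules in p order", {
  universe <- sprintf("g%d", 1:30)
  ann <- list(
    small = universe[1:4],          # < 5 genes
    top = universe[1:10],
    nested = universe[1:10],        # 100% inside `top`
    partial = c(universe[1:8], universe[20:21]))  # 80% inside `top`
  res <- data.frame(category_id = names(ann),
                    p = c(0.001, 0.0005, 0.002, 0.003),
                    significant = c(TRUE, TRUE, TRUE, TRUE),
                    stringsAsFactors = FALSE)
  out <- prune_categories(res, ann, universe)
  expect_identical(out$prune_reason[out$category_id == "small"], "too_small")
  expect_identical(out$prune_reason[out$category_id == "nested"],
                   "redundant")
  expect_identical(out$prune_reason[out$category_id == "partial"], "none")
  expect_false(any(out$significant & out$pruned))
  # sorted by (p, id)
  expect_identical(out$category_id,
                   c("top", "small", "nested", "partial"))

  # order stability: shuffling the input changes nothing
  out2 <- prune_categories(res[c(3, 1, 4, 2), ], ann, universe)
  expect_identical(out, out2)

  # a pruned category never causes pruning of another: `shadow` is fully
  # inside `nested` (pruned) but only 50% inside retained `top`
  ann2 <- c(ann, list(shadow = universe[c(1:5, 11:15)]))
  res2 <- rbind(res, data.frame(category_id = "shadow", p = 0.004,
                                significant = TRUE))
  out3 <- prune_categories(res2, ann2, universe)
  expect_identical(out3$prune_reason[out3$category_id == "shadow"], "none")

  # equal p-values do not prune each other (strictly lower p accumulates)
  ann3 <- list(a = universe[1:10], b = universe[1:10])
  res3 <- data.frame(category_id = c("a", "b"), p = c(0.01, 0.01),
                     significant = c(TRUE, TRUE))
  out4 <- prune_categories(res3, ann3, universe)
  expect_identical(out4$prune_reason, c("none", "none"))
})

test_that("run_enrichment ranks a planted category first and handles nulls", {
  universe <- sprintf("g%d", 1:50)
  fg <- universe[1:8]
  ann <- list(planted = universe[1:8], broad = universe[1:25],
              off = universe[30:45])
  res <- run_enrichment(fg, universe, ann, n_perms = 300, seed = 6)
  expect_identical(res$category_id[1], "planted")
  expect_true(res$significant[1])
  expect_identical(res$n_category_in_foreground[
    res$category_id == "planted"], 8L)

  empty <- run_enrichment(character(0), universe, ann, n_perms = 10,
                          seed = 6)
  expect_true(all(empty$p == 1))
  expect_false(any(empty$significant))

  expect_error(run_enrichment(c("zz"), universe, ann), "subset")
  expect_error(run_enrichment(fg, character(0), ann), "empty universe")

  # null foreground: raw p < 0.1 happens, significance after FWER does not
  nulls <- withr::with_seed(707, {
    vapply(1:20, function(s) {
      fgr <- sample(universe, 8)
      r <- run_enrichment(fgr, universe, ann, n_perms = 200,
                          seed = 800 + s)
      c(raw = mean(r$p < 0.1), sig = sum(r$significant))
    }, numeric(2))
  })
  expect_lt(mean(nulls["raw", ]), 0.35)
  expect_lte(mean(nulls["sig", ] > 0), 0.15)
})
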