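#' Cascade counts from per-gene cell-line tallies
#'
#' @param n_de Integer vector: for each gene, the number of cell lines in
#'   which it was called differentially expressed.
#' @param max_k Largest `k` to report (default: the observed maximum).
#' @return Data frame with `k`, `n_ge_k` (genes DE in at least `k` lines)
#'   and `n_exact_k` (genes DE in exactly `k` lines), for `k = 1..max_k`.
#' @export
cascade_counts <- function(n_de, max_k = NULL) {
  n_de <- n_de[n_de > 0]
  if (is.null(max_k)) max_k <- if (length(n_de)) max(n_de) else 1L
  k <- seq_len(max_k)
  data.frame(k = k,
             n_ge_k = vapply(k, function(x) sum(n_de >= x), integer(1)),
             n_exact_k = vapply(k, function(x) sum(n_de == x), integer(1)))
}

#' Aggregate per-cell-line DE results across the panel
#'
#' Counts, per gene, the cell lines in which it was called DE, builds the
#' cascade of genes DE in at least / exactly `k` lines, and emits a per-gene
#' direction table in the style of the publication's summary tables: `up` /
#' `down` for the sign of the normalized mean change, a `*` suffix for a
#' significant call, `NA` when the gene was not tested (not expressed) in
#' that line. Cell lines with zero DE genes are retained.
#'
#' @param de_results Named list of [run_de()] results, one per cell line.
#' @return List with `table` (data frame: `gene_id`, `n_cell_lines_de`, one
#'   direction column per cell line; genes DE in >= 1 line, sorted by
#'   descending `n_cell_lines_de` then gene id) and `cascade` (see
#'   [cascade_counts()], `max_k` = number of cell lines).
#' @export
aggregate_de <- function(de_results) {
  lines <- names(de_results)
  if (is.null(lines) || anyDuplicated(lines)) {
    stop("de_results must be uniquely named by cell line")
  }
  de_sets <- lapply(de_results, `[[`, "de_genes")
  tally <- table(unlist(de_sets, use.names = FALSE))
  genes <- if (is.null(names(tally))) character(0) else names(tally)
  cnt <- as.integer(tally)
  o <- order(-cnt, genes)
  genes <- genes[o]

  tab <- data.frame(gene_id = genes, n_cell_lines_de = cnt[o],
                    stringsAsFactors = FALSE, row.names = NULL)
  for (cl in lines) {
    res <- de_results[[cl]]$results
    dir <- res$direction[match(genes, res$gene_id)]
    sig <- genes %in% de_sets[[cl]]
    sym <- ifelse(is.na(dir), NA_character_,
                  paste0(ifelse(dir == 1L, "up", "down"),
                         ifelse(sig, "*", "")))
    tab[[cl]] <- sym
  }
  list(table = tab,
       cascade = cascade_counts(tab$n_cell_lines_de,
                                max_k = length(lines)))
}

stage_seed <- function(seed, stage) {
  derive_seed(seed, sum(utf8ToInt(stage)))
}

#' Default pipeline configuration
#'
#' @param out_dir Output directory for tables and the manifest.
#' @param synth A [synth_config()] to simulate inputs, or `NULL` to load
#'   counts from `counts_path`/`design_path`.
#' @param counts_path,design_path Input TSVs when not simulating.
#' @param annotations_path Optional long-format category annotation TSV.
#' @param reference_list_path Optional external gene list (one id per line).
#' @param padj DE call threshold (default 0.01).
#' @param run_permutation Whether to run the exhaustive label permutation
#'   stage (default TRUE).
#' @param max_perms Cap on evaluated relabelings per cell line.
#' @param overlap_draws Draws per cell-line pair for the overlap null
#'   (default 10000).
#' @param list_overlap_draws Random sets for the external-list overlap
#'   (default 1000).
#' @param min_cell_lines_foreground Foreground for enrichment and the
#'   external-list overlap: genes DE in at least this many lines (default 2).
#' @param enrich_p,enrich_fwer,enrich_min_size,enrich_redundancy,enrich_perms
#'   Enrichment parameters (defaults 0.1, 0.1, 5, 0.9, 1000).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, synth = NULL, counts_path = NULL,
                       design_path = NULL, annotations_path = NULL,
                       reference_list_path = NULL, padj = 0.01,
                       run_permutation = TRUE, max_perms = Inf,
                       overlap_draws = 10000L, list_overlap_draws = 1000L,
                       min_cell_lines_foreground = 2L,
                       enrich_p = 0.1, enrich_fwer = 0.1,
                       enrich_min_size = 5L, enrich_redundancy = 0.9,
                       enrich_perms = 1000L, seed = 1L) {
  stopifnot(padj > 0, padj <= 1, enrich_p > 0, enrich_p <= 1,
            enrich_fwer > 0, enrich_fwer <= 1,
            enrich_redundancy > 0, enrich_redundancy <= 1)
  if (is.null(synth) && (is.null(counts_path) || is.null(design_path))) {
    stop("either a synth config or counts/design paths are required")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline from one configuration
#'
#' Simulate-or-load counts, per-cell-line DE, optional exhaustive label
#' permutation, cross-panel aggregation, pairwise overlap z-scores,
#' direction concordance, and (when annotation / reference inputs are given)
#' category enrichment and external-list overlap. Every stage writes its
#' table under `out_dir`; a JSON manifest records seeds, thresholds and
#' output row counts. Identical config and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, ...) {
    message(sprintf("[crossde:%s] %s", stage, sprintf(...)))
  }
  manifest <- list(seed = config$seed, padj = config$padj,
                   thresholds = list(
                     enrich_p = config$enrich_p,
                     enrich_fwer = config$enrich_fwer,
                     enrich_min_size = config$enrich_min_size,
                     enrich_redundancy = config$enrich_redundancy),
                   stages = list())

  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- input stage -----------------------------------------------------
  if (!is.null(config$synth)) {
    sim <- with_stage("simulate", generate_counts(config$synth))
    datasets <- sim$datasets
    truth <- sim$truth
    write_table(truth, file.path(config$out_dir, "truth.tsv"))
    log_stage("simulate", "%d cell lines, %d genes, %d plantings",
              length(datasets), config$synth$n_genes, nrow(truth))
  } else {
    ds <- with_stage("load", read_counts(config$counts_path,
                                         config$design_path))
    datasets <- lapply(split(ds$design$sample_id, ds$design$cell_line),
                       function(samp) {
                         new_count_dataset(
                           ds$counts[, samp, drop = FALSE],
                           ds$design[ds$design$sample_id %in% samp, ,
                                     drop = FALSE])
                       })
    truth <- NULL
    log_stage("load", "%d cell lines, %d genes", length(datasets),
              nrow(ds$counts))
  }
  lines <- names(datasets)
  manifest$stages$input <- list(cell_lines = lines)

  # --- per-cell-line DE ------------------------------------------------
  de_results <- lapply(lines, function(cl) {
    de <- with_stage("de", run_de(datasets[[cl]], cl,
                                  padj_threshold = config$padj))
    log_stage("de", "%s: %d expressed, %d DE", cl,
              length(de$expressed), length(de$de_genes))
    write_table(de$results,
                file.path(config$out_dir, sprintf("de_%s.tsv", cl)))
    de
  })
  names(de_results) <- lines
  manifest$stages$de <- lapply(de_results, function(d)
    list(expressed = length(d$expressed), de = length(d$de_genes)))

  # --- permutation FDR -------------------------------------------------
  perm <- NULL
  if (isTRUE(config$run_permutation)) {
    perm <- lapply(lines, function(cl) {
      ps <- with_stage("permute", permutation_de_counts(
        datasets[[cl]], cl, padj_threshold = config$padj,
        max_perms = config$max_perms,
        seed = stage_seed(config$seed, paste0("permute:", cl))))
      log_stage("permute", "%s: real %d, max perm %d", cl,
                ps$real_de_count, max(ps$perm_de_counts))
      ps
    })
    names(perm) <- lines
    perm_tab <- do.call(rbind, lapply(perm, function(p) data.frame(
      cell_line = p$cell_line, real_de_count = p$real_de_count,
      max_perm_de_count = max(p$perm_de_counts),
      mean_perm_de_count = mean(p$perm_de_counts),
      n_relabelings = length(p$perm_de_counts),
      ratio_max = p$ratio_max, ratio_mean = p$ratio_mean,
      stringsAsFactors = FALSE)))
    write_table(perm_tab, file.path(config$out_dir, "permutation.tsv"))
    manifest$stages$permutation <- perm_tab
  }

  # --- aggregation -----------------------------------------------------
  agg <- with_stage("aggregate", aggregate_de(de_results))
  write_table(agg$table, file.path(config$out_dir, "aggregate.tsv"))
  write_table(agg$cascade, file.path(config$out_dir, "cascade.tsv"))
  log_stage("aggregate", "%d genes DE in >= 1 cell line", nrow(agg$table))
  manifest$stages$aggregate <- list(cascade = agg$cascade)

  # --- concordance -----------------------------------------------------
  de_sets <- lapply(de_results, `[[`, "de_genes")
  expressed_sets <- lapply(de_results, `[[`, "expressed")
  overlaps <- NULL
  if (length(lines) >= 2L) {
    overlaps <- with_stage("overlap", overlap_zscores(
      de_sets, expressed_sets, n_draws = config$overlap_draws,
      seed = stage_seed(config$seed, "overlap")))
    write_table(overlaps, file.path(config$out_dir, "overlap_z.tsv"))
    log_stage("overlap", "%d pairs, %d with z >= 5", nrow(overlaps),
              sum(overlaps$z >= 5, na.rm = TRUE))
    manifest$stages$overlap <- list(n_pairs = nrow(overlaps),
                                    n_z_ge_5 = sum(overlaps$z >= 5,
                                                   na.rm = TRUE))
  }
  dirs <- with_stage("direction", direction_summary(de_results))
  write_table(dirs, file.path(config$out_dir, "direction.tsv"))

  # --- external-list overlap and enrichment ----------------------------
  fg <- agg$table$gene_id[
    agg$table$n_cell_lines_de >= config$min_cell_lines_foreground]
  univ <- Reduce(union, expressed_sets)

  list_overlap <- NULL
  if (!is.null(config$reference_list_path) && length(fg)) {
    ref <- read_gene_list(config$reference_list_path)
    # universe: genes expressed in at least `min_cell_lines_foreground` lines
    expr_tally <- table(unlist(expressed_sets, use.names = FALSE))
    univ2 <- names(expr_tally)[
      expr_tally >= config$min_cell_lines_foreground]
    list_overlap <- with_stage("list_overlap", list_overlap_empirical_p(
      fg, ref, univ2, n_draws = config$list_overlap_draws,
      seed = stage_seed(config$seed, "list_overlap")))
    jsonlite::write_json(list_overlap,
                         file.path(config$out_dir, "list_overlap.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("list_overlap", "observed %d, empirical p %.4f",
              list_overlap$observed, list_overlap$empirical_p)
  }

  enrich <- NULL
  if (!is.null(config$annotations_path) && length(fg)) {
    ann <- read_annotations(config$annotations_path)
    enrich <- with_stage("enrich", run_enrichment(
      intersect(fg, univ), univ, ann,
      p_threshold = config$enrich_p, fwer_threshold = config$enrich_fwer,
      min_size = config$enrich_min_size,
      redundancy = config$enrich_redundancy,
      n_perms = config$enrich_perms,
      seed = stage_seed(config$seed, "enrich")))
    write_table(enrich, file.path(config$out_dir, "enrichment.tsv"))
    log_stage("enrich", "%d categories, %d significant", nrow(enrich),
              sum(enrich$significant))
  }

  manifest$stages$foreground <- list(n_genes = length(fg))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(datasets = datasets, truth = truth,
                 de_results = de_results, permutation = perm,
                 aggregate = agg, overlaps = overlaps, direction = dirs,
                 list_overlap = list_overlap, enrichment = enrich,
                 manifest = manifest))
}
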