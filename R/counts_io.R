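#' Read a count matrix and its sample design table
#'
#' Reads an HTSeq-style gene-by-sample table of non-negative integer counts
#' (TSV, first column `gene_id`, remaining columns one per sample) together
#' with a sample design table (TSV with columns `sample_id`, `cell_line`,
#' `condition`, `replicate`). Both files are validated and reconciled: the
#' sample sets must match exactly.
#'
#' @param path Path to the count TSV.
#' @param design_path Path to the design TSV.
#' @return A list of class `count_dataset` with elements `counts` (integer
#'   matrix, genes in rows, samples in columns) and `design` (data frame with
#'   one row per sample, `condition` a factor with levels
#'   `c("treated", "control")`).
#' @export
read_counts <- function(path, design_path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || names(raw)[1] != "gene_id") {
    stop("count table must be tab-separated with first column 'gene_id'")
  }
  gene_ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- gene_ids
  design <- utils::read.delim(design_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  new_count_dataset(mat, design)
}

#' Assemble and validate a count dataset
#'
#' @param counts Numeric matrix of counts, genes in rows, samples in columns;
#'   values must be non-negative integers.
#' @param design Data frame with columns `sample_id`, `cell_line`,
#'   `condition` (values `treated`/`control`), `replicate`.
#' @return A validated `count_dataset` list.
#' @export
new_count_dataset <- function(counts, design) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in count matrix")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids in count matrix")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-integer or negative count for gene '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "integer"

  need <- c("sample_id", "cell_line", "condition", "replicate")
  if (!all(need %in% names(design))) {
    stop("design table must have columns: ", paste(need, collapse = ", "))
  }
  design$sample_id <- as.character(design$sample_id)
  design$cell_line <- as.character(design$cell_line)
  if (anyDuplicated(design$sample_id)) stop("duplicate sample ids in design")
  if (!all(design$condition %in% c("treated", "control"))) {
    stop("design condition must be 'treated' or 'control'")
  }
  design$condition <- factor(design$condition, levels = c("treated", "control"))
  if (any(design$replicate != round(design$replicate) | design$replicate < 1)) {
    stop("replicate ids must be positive integers")
  }
  dup <- duplicated(design[, c("cell_line", "condition", "replicate")])
  if (any(dup)) stop("replicate numbers must be unique within cell line and condition")

  only_m <- setdiff(colnames(counts), design$sample_id)
  only_d <- setdiff(design$sample_id, colnames(counts))
  if (length(only_m) || length(only_d)) {
    stop("sample sets of count matrix and design differ; ",
         "only in matrix: [", paste(only_m, collapse = ", "), "]; ",
         "only in design: [", paste(only_d, collapse = ", "), "]")
  }
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(list(counts = counts, design = design), class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf("count_dataset: %d genes x %d samples, %d cell line(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$design$cell_line))))
  invisible(x)
}

#' Write a result table as TSV
#'
#' Plain tab-separated output with a header row; numeric values are written at
#' full precision so that a read-back reproduces them exactly.
#'
#' @param records Data frame to write (may have zero rows).
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records)) stop("records must be a data frame")
  if (ncol(records) == 0L) stop("records must have at least one column")
  # full-precision doubles so a read-back reproduces every value exactly
  for (j in seq_along(records)) {
    if (is.double(records[[j]])) {
      records[[j]] <- ifelse(is.na(records[[j]]), NA,
                             sprintf("%.17g", records[[j]]))
    }
  }
  ok <- tryCatch({
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write table to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a result table written by [write_table()]
#' @param path Path to a TSV with header.
#' @return Data frame.
#' @export
read_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a gene list (one id per line)
#' @param path Path to a text file, one gene id per line.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path)
  ids <- ids[nzchar(trimws(ids))]
  unique(trimws(ids))
}

#' Read a long-format category annotation table
#'
#' Expects a TSV with columns `category_id`, `category_name`, `gene_id`, one
#' row per (category, gene) assignment, gene membership already propagated
#' through any ontology hierarchy upstream.
#'
#' @param path Path to the annotation TSV.
#' @return A named list of character vectors (gene ids per category), with a
#'   `category_names` attribute mapping category ids to display names.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("category_id", "category_name", "gene_id")
  if (!all(need %in% names(tab))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  ann <- split(as.character(tab$gene_id), tab$category_id)
  ann <- lapply(ann, unique)
  nm <- tapply(as.character(tab$category_name), tab$category_id,
               function(x) x[1])
  attr(ann, "category_names") <- nm[names(ann)]
  ann
}

#' Load the packaged differential-expression cascade fixture
#'
#' Returns the packaged per-gene table of how many cell lines called each gene
#' differentially expressed in the ten-cell-line overexpression panel. The
#' gene names printed in the publication (the >=4-cell-line stratum and a few
#' named genes below it) are real; the remaining identifiers are synthetic
#' placeholders, as the full supplementary table is not redistributable —
#' hence the `_synthetic` filename. The cascade counts per stratum match the
#' published figures exactly.
#'
#' @return Data frame with columns `gene_id` and `n_cell_lines_de`.
#' @export
load_s2_fixture <- function() {
  path <- system.file("extdata", "table_s2_synthetic.tsv", package = "crossde")
  if (path == "" || !file.exists(path)) {
    stop("fixture 'extdata/table_s2_synthetic.tsv' not found; ",
         "reinstall the package (the fixture ships under inst/extdata/)")
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(identical(names(tab), c("gene_id", "n_cell_lines_de")))
  tab
}

#' Between-sample rank correlations of log-scale normalized expression
#'
#' Computes Spearman correlations between all sample pairs on
#' `log2(count / size_factor + 1)`. The log transform is monotone, so the
#' rank correlation is unaffected by its base; normalization removes
#' library-size rank distortion only when genes tie after scaling.
#'
#' @param dataset A `count_dataset`.
#' @return Symmetric matrix of Spearman correlations with unit diagonal.
#' @export
qc_sample_correlations <- function(dataset) {
  counts <- dataset$counts
  if (ncol(counts) < 2L) stop("need at least two samples for QC correlations")
  sf <- estimate_size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  m <- stats::cor(log2(norm + 1), method = "spearman")
  diag(m) <- 1
  m
}
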