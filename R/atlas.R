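#' Construct an expression atlas
#'
#' Container for a cells x genes count matrix with cell and gene
#' annotations, plus (after [preprocess()]) a log-normalized layer
#' `log(1 + 10^4 * count / cell_total)`.
#'
#' @param counts Cells x genes matrix of non-negative integers (coerced to
#'   a sparse `dgCMatrix`).
#' @param cells Data frame with at least `cell_id`, `age_months`, `sex`,
#'   `tissue`, `cell_type`; optional `functional_category`,
#'   `lifespan_label`.
#' @param genes Character vector of gene identifiers (columns of `counts`).
#' @param lognorm Optional precomputed log-normalized layer.
#' @return An object of class `expression_atlas` with fields `counts`,
#'   `lognorm`, `cells`, `genes`.
#' @export
expression_atlas <- function(counts, cells, genes, lognorm = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  required <- c("cell_id", "age_months", "sex", "tissue", "cell_type")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0)
    stop("load error: cell annotation is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(cells) != nrow(counts))
    stop("load error: dimension mismatch: ", nrow(counts),
         " matrix rows vs ", nrow(cells), " cell annotation rows")
  if (length(genes) != ncol(counts))
    stop("load error: dimension mismatch: ", ncol(counts),
         " matrix columns vs ", length(genes), " gene annotation rows")
  neg <- which(counts@x < 0)
  if (length(neg) > 0) {
    ij <- which(as.matrix(counts < 0), arr.ind = TRUE)[1, ]
    stop("load error: negative count at cell '", cells$cell_id[ij[1]],
         "', gene '", genes[ij[2]], "'")
  }
  bad_sex <- setdiff(unique(cells$sex), c("male", "female"))
  if (length(bad_sex) > 0)
    stop("load error: sex must be 'male' or 'female'; found: ",
         paste(bad_sex, collapse = ", "))
  rownames(counts) <- cells$cell_id
  colnames(counts) <- genes
  structure(list(counts = counts, lognorm = lognorm,
                 cells = cells, genes = as.character(genes)),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat("expression_atlas:", nrow(x$counts), "cells x", ncol(x$counts),
      "genes\n")
  cat("  tissues:", paste(unique(x$cells$tissue), collapse = ", "), "\n")
  cat("  ages (months):",
      paste(sort(unique(x$cells$age_months)), collapse = ", "), "\n")
  cat("  log-normalized layer:",
      if (is.null(x$lognorm)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
dim.expression_atlas <- function(x) dim(x$counts)

#' Load an expression atlas from Matrix Market + TSV files
#'
#' @param counts_path Matrix Market (.mtx) file, cells x genes.
#' @param cells_path Tab-delimited cell annotation with header
#'   (`cell_id`, `age_months`, `sex`, `tissue`, `cell_type`, ...).
#' @param genes_path Tab-delimited gene table with header; first column is
#'   the gene identifier.
#' @return An [expression_atlas()].
#' @export
load_atlas <- function(counts_path, cells_path, genes_path) {
  counts <- readMM(counts_path)
  cells <- read.delim(cells_path, stringsAsFactors = FALSE)
  genes <- read.delim(genes_path, stringsAsFactors = FALSE)[[1]]
  expression_atlas(counts, cells, genes)
}

#' Write an expression atlas to Matrix Market + TSV files
#'
#' Writes `counts.mtx`, `cells.tsv` and `genes.tsv` into `dir`; the
#' inverse of [load_atlas()] for raw counts.
#'
#' @param atlas An [expression_atlas()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeMM(atlas$counts, file.path(dir, "counts.mtx"))
  write.table(atlas$cells, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = atlas$genes), file.path(dir, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Filter and normalize an atlas
#'
#' Applies, in order: a gene filter (genes expressed, count > 0, in fewer
#' than `min_cells_per_gene` cells are removed; applied once, not
#' iterated), cell filters (cells expressing fewer than
#' `min_genes_per_cell` genes or with total counts below
#' `min_counts_per_cell` are removed), then per-cell normalization to
#' 10,000 counts followed by a natural-log `log(x + 1)` transform.
#'
#' Presets reproduce the standard filter sets: `facs` (3 cells, 250
#' genes, 5000 counts), `droplet` (3 cells, 250 genes, 2500 UMIs), `bulk`
#' (5 samples, 500 genes, no count filter).
#'
#' @param atlas An [expression_atlas()] with raw counts.
#' @param min_cells_per_gene,min_genes_per_cell,min_counts_per_cell
#'   Filter thresholds; overridden by `preset` when given.
#' @param preset One of `"facs"`, `"droplet"`, `"bulk"`, or `NULL` to use
#'   the explicit thresholds.
#' @return The filtered atlas with the `lognorm` layer populated.
#' @export
preprocess <- function(atlas, min_cells_per_gene = 3,
                       min_genes_per_cell = 250,
                       min_counts_per_cell = 5000,
                       preset = NULL) {
  stopifnot(inherits(atlas, "expression_atlas"))
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("facs", "droplet", "bulk"))
    th <- switch(preset,
      facs = c(3, 250, 5000),
      droplet = c(3, 250, 2500),
      bulk = c(5, 500, 0))
    min_cells_per_gene <- th[1]
    min_genes_per_cell <- th[2]
    min_counts_per_cell <- th[3]
  }
  counts <- atlas$counts
  keep_g <- colSums(counts > 0) >= min_cells_per_gene
  counts <- counts[, keep_g, drop = FALSE]
  n_expr <- rowSums(counts > 0)
  total <- rowSums(counts)
  keep_c <- n_expr >= min_genes_per_cell & total >= min_counts_per_cell
  counts <- counts[keep_c, , drop = FALSE]
  if (nrow(counts) == 0 || ncol(counts) == 0)
    stop("empty result: no ", if (nrow(counts) == 0) "cells" else "genes",
         " survive the filters")
  total <- rowSums(counts)
  lognorm <- log1p(Matrix::Diagonal(x = 1e4 / total) %*% counts)
  lognorm <- as(as(lognorm, "CsparseMatrix"), "generalMatrix")
  expression_atlas(counts, atlas$cells[keep_c, , drop = FALSE],
                   atlas$genes[keep_g], lognorm = lognorm)
}

#' Eligible tissue-cell-type groups and tissue weights
#'
#' A (tissue, cell type) group is eligible when it has at least
#' `min_cells` cells in the young age set and at least `min_cells` in the
#' old age set. Each eligible group receives weight 1 / (number of
#' eligible cell types in its tissue), so a tissue's weights sum to 1.
#'
#' @param atlas An [expression_atlas()].
#' @param young_ages,old_ages Numeric age sets (months) defining young and
#'   old cells; defaults 3 vs pooled 18 and 24.
#' @param min_cells Minimum cells required in each age set (default 100;
#'   use 500 for the droplet regime).
#' @return Data frame with one row per eligible group: `tissue`,
#'   `cell_type`, `group` key, `n_young`, `n_old`, `n_cells`, `weight`,
#'   and carried-over `functional_category` / `lifespan_label`.
#' @export
eligible_groups <- function(atlas, young_ages = 3, old_ages = c(18, 24),
                            min_cells = 100) {
  if (length(young_ages) == 0 || length(old_ages) == 0)
    stop("configuration error: young and old age sets must be non-empty")
  cells <- atlas$cells
  key <- group_key(cells$tissue, cells$cell_type)
  uk <- unique(key)
  info <- cells[match(uk, key), c("tissue", "cell_type"), drop = FALSE]
  n_young <- vapply(uk, function(k)
    sum(key == k & cells$age_months %in% young_ages), 0L)
  n_old <- vapply(uk, function(k)
    sum(key == k & cells$age_months %in% old_ages), 0L)
  eligible <- n_young >= min_cells & n_old >= min_cells
  out <- data.frame(
    tissue = info$tissue, cell_type = info$cell_type, group = uk,
    n_young = as.integer(n_young), n_old = as.integer(n_old),
    n_cells = as.integer(tabulate(match(key, uk), length(uk))),
    stringsAsFactors = FALSE
  )[eligible, , drop = FALSE]
  n_types <- table(out$tissue)
  out$weight <- 1 / as.numeric(n_types[out$tissue])
  for (col in c("functional_category", "lifespan_label")) {
    out[[col]] <- if (col %in% names(cells))
      cells[[col]][match(out$group, key)]
    else rep(NA_character_, nrow(out))
  }
  rownames(out) <- NULL
  out
}

#' Per-cell QC covariates and their correlation with age and depth
#'
#' Reports, per cell, the number of expressed genes (count > 0; the
#' cellular detection rate, CDR) and the total count, together with
#' Pearson and Spearman correlations of CDR against age and against
#' depth. These diagnostics motivate leaving CDR out of the
#' differential-expression design.
#'
#' @param atlas An [expression_atlas()] with counts.
#' @return A list of class `cell_qc`: `$table` (per-cell data frame) and
#'   `$correlations` (variable pair, method, estimate).
#' @export
cell_qc <- function(atlas) {
  counts <- atlas$counts
  tab <- data.frame(
    cell_id = atlas$cells$cell_id,
    n_expressed_genes = as.integer(rowSums(counts > 0)),
    total_counts = as.numeric(rowSums(counts)),
    stringsAsFactors = FALSE
  )
  age <- atlas$cells$age_months
  cors <- expand.grid(pair = c("cdr_vs_age", "cdr_vs_depth"),
                      method = c("pearson", "spearman"),
                      stringsAsFactors = FALSE)
  cors$estimate <- mapply(function(pair, method) {
    y <- if (pair == "cdr_vs_age") age else tab$total_counts
    suppressWarnings(cor(tab$n_expressed_genes, y, method = method))
  }, cors$pair, cors$method)
  structure(list(table = tab, correlations = cors), class = "cell_qc")
}

#' @export
print.cell_qc <- function(x, ...) {
  cat("cell_qc over", nrow(x$table), "cells\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
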