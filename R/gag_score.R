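#' Per-cell GAG score with random-background z-normalization
#'
#' The raw score of a cell is the mean log-normalized expression over the
#' upregulated GAGs minus the mean over the downregulated GAGs. It is
#' z-normalized against the null of two random gene sets of the same
#' sizes: a difference of means of `n_up` and `n_down` randomly chosen
#' genes has expectation 0 and standard deviation
#' `cell_std * sqrt(1/n_up + 1/n_down)`, where `cell_std` is the
#' (population) standard deviation of the cell's expression across genes.
#'
#' Gene lists are intersected with the atlas's genes first, so a dataset
#' missing some GAGs is scored on the genes it has; unknown identifiers
#' are reported as a warning with counts. Cells with zero expression
#' variance get an `NA` score and `undefined = TRUE`.
#'
#' @param atlas A preprocessed [expression_atlas()].
#' @param up_genes,down_genes Character vectors of up-/downregulated
#'   GAGs; each must be non-empty after intersection with the atlas.
#' @param std_gene_set `"all"` (default): `cell_std` over all genes;
#'   `"expressed"`: over the cell's expressed (non-zero) genes only.
#' @param gene_weights Optional named per-gene weights replacing the
#'   unweighted means (used by [compute_gag_score_weighted()]).
#' @return Data frame with `cell_id`, `raw_score`, `score`, `n_up`,
#'   `n_down`, `cell_std`, `undefined`.
#' @examples
#' sim <- simulate_atlas(simulation_config(cells_per_type_per_age = 20,
#'                                         n_genes = 200))
#' at <- preprocess(sim$atlas)
#' cls <- sim$truth$gene_classes
#' sc <- compute_gag_score(at, cls$gene[cls$class == "global_up"],
#'                         cls$gene[cls$class == "global_down"])
#' head(sc)
#' @export
compute_gag_score <- function(atlas, up_genes, down_genes,
                              std_gene_set = c("all", "expressed"),
                              gene_weights = NULL) {
  std_gene_set <- match.arg(std_gene_set)
  if (is.null(atlas$lognorm))
    stop("atlas has no log-normalized layer; run preprocess() first")
  up_genes <- unique(up_genes); down_genes <- unique(down_genes)
  unknown <- sum(!up_genes %in% atlas$genes) +
    sum(!down_genes %in% atlas$genes)
  if (unknown > 0)
    warning(unknown, " gene id(s) not present in the atlas were dropped")
  up <- intersect(up_genes, atlas$genes)
  down <- intersect(down_genes, atlas$genes)
  if (length(up) == 0)
    stop("up-gene list is empty after intersection with the atlas")
  if (length(down) == 0)
    stop("down-gene list is empty after intersection with the atlas")

  ln <- atlas$lognorm
  mean_of <- function(genes) {
    sub <- ln[, match(genes, atlas$genes), drop = FALSE]
    if (is.null(gene_weights)) {
      as.numeric(rowSums(sub)) / length(genes)
    } else {
      w <- gene_weights[genes]
      if (sum(w) == 0) stop("all gene weights are zero within a list")
      as.numeric(sub %*% w) / sum(w)
    }
  }
  raw <- mean_of(up) - mean_of(down)

  G <- length(atlas$genes)
  row_mean <- as.numeric(rowSums(ln)) / G
  row_mean2 <- as.numeric(rowSums(ln^2)) / G
  if (std_gene_set == "all") {
    cell_std <- sqrt(pmax(row_mean2 - row_mean^2, 0))
  } else {
    k <- as.numeric(rowSums(ln > 0))
    m1 <- as.numeric(rowSums(ln)) / pmax(k, 1)
    m2 <- as.numeric(rowSums(ln^2)) / pmax(k, 1)
    cell_std <- sqrt(pmax(m2 - m1^2, 0))
  }
  denom <- cell_std * sqrt(1 / length(up) + 1 / length(down))
  undefined <- cell_std == 0
  score <- ifelse(undefined, NA_real_, raw / denom)
  # raw = 0 everywhere when the lists coincide; keep score 0, not 0/0 noise
  score[!undefined & raw == 0] <- 0
  data.frame(cell_id = atlas$cells$cell_id, raw_score = raw,
             score = score, n_up = length(up), n_down = length(down),
             cell_std = cell_std, undefined = undefined,
             stringsAsFactors = FALSE)
}

#' Score an external dataset with a reference GAG set
#'
#' Applies [compute_gag_score()] to another atlas (e.g. a droplet dataset
#' or a bulk dataset whose samples are treated as cells) using GAG lists
#' defined on a reference dataset; genes absent from the target atlas are
#' dropped by the intersection contract.
#'
#' @param atlas_other A preprocessed [expression_atlas()].
#' @param gag_sets Either the list returned by [select_gags()] or a data
#'   frame with columns `gene` and `class` (values `global_up` /
#'   `global_down`).
#' @param ... Passed to [compute_gag_score()].
#' @return As [compute_gag_score()].
#' @export
score_external <- function(atlas_other, gag_sets, ...) {
  if (is.data.frame(gag_sets)) {
    up <- gag_sets$gene[gag_sets$class == "global_up"]
    down <- gag_sets$gene[gag_sets$class == "global_down"]
  } else {
    up <- gag_sets$global_up
    down <- gag_sets$global_down
  }
  compute_gag_score(atlas_other, up, down, ...)
}

#' Expression-range-weighted GAG score
#'
#' Variant of [compute_gag_score()] in which each gene's contribution to
#' the up/down means is weighted by its expression range (max - min of
#' its log-normalized expression across cells), for checking robustness
#' to highly expressed genes.
#'
#' @inheritParams compute_gag_score
#' @return As [compute_gag_score()].
#' @export
compute_gag_score_weighted <- function(atlas, up_genes, down_genes,
                                       std_gene_set = c("all", "expressed")) {
  if (is.null(atlas$lognorm))
    stop("atlas has no log-normalized layer; run preprocess() first")
  ln <- atlas$lognorm
  rng <- apply(as.matrix(ln), 2, function(x) max(x) - min(x))
  names(rng) <- atlas$genes
  compute_gag_score(atlas, up_genes, down_genes,
                    std_gene_set = std_gene_set, gene_weights = rng)
}
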