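#' Enumerate tissue-cell-type sets at a grouping level
#'
#' Builds one set of tissue-cell-type keys per distinct label at the
#' requested level: functional category, cell type (pooled across
#' tissues), tissue, or single tissue-cell type.
#'
#' @param groups Data frame from [eligible_groups()].
#' @param level One of `"category"`, `"cell_type"`, `"tissue"`,
#'   `"tissue_cell_type"`.
#' @return Named list of character vectors of group keys.
#' @export
enumerate_sets <- function(groups,
                           level = c("category", "cell_type", "tissue",
                                     "tissue_cell_type")) {
  level <- match.arg(level)
  lab <- switch(level,
    category = groups$functional_category,
    cell_type = groups$cell_type,
    tissue = groups$tissue,
    tissue_cell_type = groups$group)
  keep <- !is.na(lab)
  labs <- unique(lab[keep])
  if (length(labs) < 2)
    stop("level '", level, "' has fewer than 2 labels; no outside set exists")
  stats::setNames(lapply(labs, function(l) groups$group[keep & lab == l]),
                  labs)
}

#' Genes with aging effects specific to a set of tissue-cell types
#'
#' For each gene, pools its per-group age coefficients by random-effects
#' meta-analysis separately inside and outside the given set of
#' tissue-cell types. A gene is set-specific when all three hold:
#' the within- and outside-set pooled coefficients differ significantly
#' (`z = (within - outside) / sqrt(se_w^2 + se_o^2)`, BH-adjusted over
#' all genes, `diff_q < fdr`); the within-set coefficient is large
#' (`|within| > beta_threshold`); and the outside-set coefficient is not
#' significantly different from 0 (BH-adjusted `outside_q > fdr`). The
#' two BH corrections run independently, each across all genes. Genes
#' lacking an estimate on either side are skipped (attribute
#' `"n_skipped"`).
#'
#' @param records Output of [run_dge()] (uses `beta_age` and `se_age`).
#' @param set_groups Character vector of tissue-cell-type keys; must be a
#'   non-empty strict subset of the groups present in `records`.
#' @param fdr FDR level for both criteria (default 0.01).
#' @param beta_threshold Minimum absolute within-set pooled coefficient
#'   (default 0.005, natural-log fold change per month).
#' @param set_name Label carried into the output.
#' @return Data frame with one row per gene: within/outside pooled
#'   estimates and ses, `diff_p`/`diff_q`, `outside_p`/`outside_q`,
#'   `specific`.
#' @export
set_specific_genes <- function(records, set_groups, fdr = 0.01,
                               beta_threshold = 0.005,
                               set_name = "set") {
  key <- group_key(records$tissue, records$cell_type)
  all_groups <- unique(key)
  if (length(set_groups) == 0)
    stop("set_groups is empty")
  if (!all(set_groups %in% all_groups))
    stop("set contains unknown group(s): ",
         paste(setdiff(set_groups, all_groups), collapse = ", "))
  if (length(setdiff(all_groups, set_groups)) == 0)
    stop("set equals all groups; the outside set is empty")

  genes <- unique(records$gene)
  K <- length(all_groups)
  B <- SE <- matrix(NA_real_, K, length(genes),
                    dimnames = list(all_groups, genes))
  idx <- cbind(match(key, all_groups), match(records$gene, genes))
  B[idx] <- records$beta_age
  SE[idx] <- records$se_age

  inside <- all_groups %in% set_groups
  wi <- .dl_meta(B[inside, , drop = FALSE], SE[inside, , drop = FALSE])
  ou <- .dl_meta(B[!inside, , drop = FALSE], SE[!inside, , drop = FALSE])
  usable <- wi$K >= 1 & ou$K >= 1
  n_skipped <- sum(!usable)

  diff_z <- (wi$estimate - ou$estimate) / sqrt(wi$se^2 + ou$se^2)
  diff_p <- 2 * pnorm(-abs(diff_z))
  outside_p <- 2 * pnorm(-abs(ou$estimate / ou$se))
  diff_q <- outside_q <- rep(NA_real_, length(genes))
  diff_q[usable] <- bh_adjust(diff_p[usable])
  outside_q[usable] <- bh_adjust(outside_p[usable])

  out <- data.frame(
    gene = genes, set_name = set_name,
    within_meta = wi$estimate, within_se = wi$se, k_within = wi$K,
    outside_meta = ou$estimate, outside_se = ou$se, k_outside = ou$K,
    diff_p = diff_p, diff_q = diff_q,
    outside_p = outside_p, outside_q = outside_q,
    stringsAsFactors = FALSE
  )[usable, , drop = FALSE]
  out$specific <- out$diff_q < fdr &
    abs(out$within_meta) > beta_threshold & out$outside_q > fdr
  attr(out, "n_skipped") <- n_skipped
  rownames(out) <- NULL
  out
}

#' Set-specific genes for every set at a grouping level
#'
#' Convenience wrapper: enumerates the sets at `level` with
#' [enumerate_sets()] and runs [set_specific_genes()] for each,
#' concatenating the results.
#'
#' @inheritParams set_specific_genes
#' @param groups Data frame from [eligible_groups()].
#' @param level Grouping level passed to [enumerate_sets()].
#' @return Row-bound data frame over all sets.
#' @export
find_specific_genes <- function(records, groups, level = "category",
                                fdr = 0.01, beta_threshold = 0.005) {
  sets <- enumerate_sets(groups, level)
  do.call(rbind, lapply(names(sets), function(nm)
    set_specific_genes(records, sets[[nm]], fdr = fdr,
                       beta_threshold = beta_threshold, set_name = nm)))
}
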