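#' Tissue-weighted significance and direction proportions per gene
#'
#' Aggregates per-group differential-expression records into, per gene,
#' the weighted proportion of tissue-cell types where the gene is
#' significantly age-dependent (`prop_sig`, denominator = total weight of
#' all eligible groups, so a gene tested in only some groups is treated
#' conservatively) and the weighted proportion of those significant
#' groups where it is upregulated (`prop_up`). With
#' `direction_denominator = "all"` the up-proportion is instead taken
#' over all eligible groups.
#'
#' Genes are classified as `not_global` when `prop_sig <= sig_threshold`;
#' otherwise `global_up` when `prop_up > direction_threshold`,
#' `global_down` when `prop_up < 1 - direction_threshold`, else
#' `global_mixed`.
#'
#' @param records Output of [run_dge()].
#' @param groups Data frame from [eligible_groups()] carrying `weight`.
#' @param sig_threshold Weighted-proportion cutoff for calling a gene
#'   global (strict `>`, default 0.5).
#' @param direction_threshold Direction-consistency cutoff (strict,
#'   default 0.8).
#' @param direction_denominator `"significant"` (default) or `"all"`.
#' @return Data frame with `gene`, `prop_sig`, `prop_up`,
#'   `n_groups_tested`, `global_class`.
#' @export
weighted_proportions <- function(records, groups, sig_threshold = 0.5,
                                 direction_threshold = 0.8,
                                 direction_denominator = c("significant", "all")) {
  direction_denominator <- match.arg(direction_denominator)
  key <- group_key(records$tissue, records$cell_type)
  w <- groups$weight[match(key, groups$group)]
  if (anyNA(w))
    stop("weight missing for group(s): ",
         paste(unique(key[is.na(w)]), collapse = ", "))
  total_w <- sum(groups$weight)
  genes <- unique(records$gene)
  gi <- match(records$gene, genes)
  sig_w <- up_w <- numeric(length(genes))
  sig <- records$significant
  up <- sig & records$direction == "up"
  sig_w <- as.numeric(rowsum(w * sig, gi, reorder = TRUE))
  up_w <- as.numeric(rowsum(w * up, gi, reorder = TRUE))
  n_tested <- as.integer(tabulate(gi, length(genes)))
  prop_sig <- sig_w / total_w
  prop_up <- if (direction_denominator == "significant") {
    ifelse(sig_w > 0, up_w / sig_w, NA_real_)
  } else up_w / total_w
  cls <- ifelse(prop_sig <= sig_threshold, "not_global",
         ifelse(prop_up > direction_threshold, "global_up",
         ifelse(prop_up < 1 - direction_threshold, "global_down",
                "global_mixed")))
  data.frame(gene = genes, prop_sig = prop_sig, prop_up = prop_up,
             n_groups_tested = n_tested, global_class = cls,
             stringsAsFactors = FALSE)
}

#' Select and partition global aging genes
#'
#' Global aging genes (GAGs) are genes significant in more than
#' `sig_threshold` of the weighted tissue-cell types; they are
#' partitioned by direction consistency into consistently up
#' (`prop_up > direction_threshold`), consistently down
#' (`prop_up < 1 - direction_threshold`) and mixed. Both inequalities are
#' strict, so a gene at exactly 80% up is classed as mixed.
#'
#' @param table Output of [weighted_proportions()].
#' @param sig_threshold,direction_threshold Selection thresholds in
#'   (0, 1).
#' @return List with character vectors `global_up`, `global_down`,
#'   `global_mixed`, their union `gags`, and the annotated `table`.
#' @export
select_gags <- function(table, sig_threshold = 0.5,
                        direction_threshold = 0.8) {
  if (sig_threshold <= 0 || sig_threshold >= 1 ||
      direction_threshold <= 0 || direction_threshold >= 1)
    stop("thresholds must lie strictly inside (0, 1)")
  is_gag <- table$prop_sig > sig_threshold
  up <- is_gag & table$prop_up > direction_threshold
  down <- is_gag & table$prop_up < 1 - direction_threshold
  mixed <- is_gag & !up & !down
  cls <- ifelse(!is_gag, "not_global",
         ifelse(up, "global_up", ifelse(down, "global_down",
                                        "global_mixed")))
  table$global_class <- cls
  list(global_up = table$gene[up], global_down = table$gene[down],
       global_mixed = table$gene[mixed], gags = table$gene[is_gag],
       table = table)
}

#' Hypergeometric overlap test between two gene sets
#'
#' One-sided enrichment test of the overlap between two gene sets drawn
#' from a common universe: `P(X >= n_overlap)` with
#' `X ~ Hypergeometric(universe, n_a, n_b)` — the one-sided Fisher exact
#' test for enrichment.
#'
#' @param set_a,set_b Character vectors; both must be subsets of
#'   `universe`.
#' @param universe Character vector of all genes considered.
#' @param set_a_name,set_b_name Labels carried into the result.
#' @return A one-row data frame of class `overlap_result`:
#'   `set_a_name`, `set_b_name`, `n_a`, `n_b`, `n_overlap`,
#'   `universe_size`, `p_value`.
#' @export
overlap_test <- function(set_a, set_b, universe,
                         set_a_name = "set_a", set_b_name = "set_b") {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) > 0 || length(out_b) > 0)
    stop("set element(s) outside the universe: ",
         paste(utils::head(c(out_a, out_b), 5), collapse = ", "))
  n_a <- length(set_a); n_b <- length(set_b)
  n_overlap <- length(intersect(set_a, set_b))
  p <- stats::phyper(n_overlap - 1, n_a, length(universe) - n_a, n_b,
                     lower.tail = FALSE)
  structure(data.frame(set_a_name = set_a_name, set_b_name = set_b_name,
                       n_a = n_a, n_b = n_b, n_overlap = n_overlap,
                       universe_size = length(universe), p_value = p,
                       stringsAsFactors = FALSE),
            class = c("overlap_result", "data.frame"))
}
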