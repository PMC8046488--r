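# Benjamini-Hochberg step-up adjustment as used throughout the package.
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Fit the per-gene age model for one gene in one tissue-cell type
#'
#' Ordinary least squares of log-normalized expression on
#' `(intercept, age, sex)` with a two-sided Wald t-test on the age
#' coefficient. If sex is constant within the group it is dropped from
#' the design. Age is in months, so the age coefficient is a natural-log
#' fold change per month.
#'
#' @param expr Numeric vector of per-cell log-normalized expression.
#' @param age Numeric vector of ages (months).
#' @param sex Character (`"male"`/`"female"`) or 0/1 numeric vector
#'   (male = 1); `NULL` to omit.
#' @return List with `beta_age`, `se_age`, `p_age`, `beta_sex` (`NA` when
#'   sex was dropped), `df_residual` and `n`.
#' @export
fit_gene_age_model <- function(expr, age, sex = NULL) {
  n <- length(expr)
  if (length(age) != n) stop("expr and age lengths differ")
  if (n < 3) stop("at least 3 cells are required")
  if (length(unique(age)) < 2)
    stop("rank deficiency: a single age value cannot identify an age effect")
  X <- cbind(intercept = 1, age = age)
  if (!is.null(sex)) {
    sex01 <- if (is.numeric(sex)) sex else as.numeric(sex == "male")
    if (length(unique(sex01)) > 1) X <- cbind(X, sex = sex01)
  }
  p <- ncol(X)
  if (n <= p) stop("more parameters than cells (n = ", n, ", p = ", p, ")")
  XtXi <- solve(crossprod(X))
  b <- drop(XtXi %*% crossprod(X, expr))
  res <- expr - drop(X %*% b)
  s2 <- sum(res^2) / (n - p)
  se <- sqrt(s2 * diag(XtXi))
  t_age <- b["age"] / se["age"]
  list(beta_age = unname(b["age"]), se_age = unname(se["age"]),
       p_age = unname(2 * pt(-abs(t_age), n - p)),
       beta_sex = if ("sex" %in% colnames(X)) unname(b["sex"]) else NA_real_,
       df_residual = n - p, n = n)
}

# vectorized OLS across all genes of one group; returns a data.frame
.fit_group <- function(Y, age, sex01) {
  n <- nrow(Y)
  X <- cbind(intercept = 1, age = age)
  if (length(unique(sex01)) > 1) X <- cbind(X, sex = sex01)
  p <- ncol(X)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% B
  s2 <- colSums(res^2) / (n - p)
  se_age <- sqrt(s2 * XtXi["age", "age"])
  t_age <- B["age", ] / se_age
  data.frame(
    gene = colnames(Y),
    beta_age = as.numeric(B["age", ]),
    se_age = as.numeric(se_age),
    p_age = as.numeric(2 * pt(-abs(t_age), n - p)),
    beta_sex = if (p == 3) as.numeric(B["sex", ]) else NA_real_,
    n_cells = n,
    stringsAsFactors = FALSE
  )
}

#' Differential expression against age for every eligible group
#'
#' For each eligible (tissue, cell type) group, regresses each gene's
#' log-normalized expression on age (continuous, months) controlling for
#' sex, then adjusts the age p-values within the group by
#' Benjamini-Hochberg over the genes tested there. A gene is flagged
#' significant when its adjusted p-value is below `fdr_threshold` and its
#' absolute age coefficient is at least `beta_threshold`. Genes with zero
#' expression variance within a group are skipped (counted in attribute
#' `"n_skipped"`), not errored.
#'
#' @param atlas A preprocessed [expression_atlas()] (lognorm layer
#'   present).
#' @param groups Data frame from [eligible_groups()].
#' @param fdr_threshold BH-adjusted p-value cutoff (default 0.01).
#' @param beta_threshold Minimum absolute age coefficient, natural-log
#'   fold change per month (default 0.005).
#' @return Data frame of per (group, gene) records: `tissue`,
#'   `cell_type`, `gene`, `beta_age`, `se_age`, `p_age`, `q_age`,
#'   `beta_sex`, `n_cells`, `significant`, `direction`.
#' @export
run_dge <- function(atlas, groups, fdr_threshold = 0.01,
                    beta_threshold = 0.005) {
  stopifnot(inherits(atlas, "expression_atlas"))
  if (is.null(atlas$lognorm))
    stop("atlas has no log-normalized layer; run preprocess() first")
  cells <- atlas$cells
  key <- group_key(cells$tissue, cells$cell_type)
  n_skipped <- 0L
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    idx <- which(key == groups$group[i])
    if (length(idx) == 0)
      stop("group '", groups$group[i], "' is absent from the atlas")
    Y <- as.matrix(atlas$lognorm[idx, , drop = FALSE])
    v <- colMeans(Y^2) - colMeans(Y)^2
    keep <- v > 0
    n_skipped <- n_skipped + sum(!keep)
    Y <- Y[, keep, drop = FALSE]
    rec <- .fit_group(Y, cells$age_months[idx],
                      as.numeric(cells$sex[idx] == "male"))
    rec$q_age <- bh_adjust(rec$p_age)
    rec$tissue <- groups$tissue[i]
    rec$cell_type <- groups$cell_type[i]
    out[[i]] <- rec
  }
  rec <- do.call(rbind, out)
  rec$significant <- rec$q_age < fdr_threshold &
    abs(rec$beta_age) >= beta_threshold
  rec$direction <- ifelse(rec$beta_age > 0, "up", "down")
  rec <- rec[, c("tissue", "cell_type", "gene", "beta_age", "se_age",
                 "p_age", "q_age", "beta_sex", "n_cells", "significant",
                 "direction")]
  attr(rec, "n_skipped") <- n_skipped
  rownames(rec) <- NULL
  rec
}

#' Up/down summary per tissue-cell type
#'
#' Counts significantly up- and downregulated genes per group, their
#' ratio, and a highlight flag for groups whose dominant direction
#' exceeds `ratio_threshold` (default 1.5x).
#'
#' @param records Output of [run_dge()].
#' @param ratio_threshold Dominance ratio above which a group is
#'   highlighted.
#' @return Data frame with `tissue`, `cell_type`, `n_up`, `n_down`,
#'   `ratio` (`n_up / n_down`; `Inf` when `n_down` is 0 and `n_up` > 0)
#'   and `highlight`.
#' @export
updown_summary <- function(records, ratio_threshold = 1.5) {
  key <- group_key(records$tissue, records$cell_type)
  uk <- unique(key)
  info <- records[match(uk, key), c("tissue", "cell_type")]
  n_up <- vapply(uk, function(k)
    sum(key == k & records$significant & records$direction == "up"), 0L)
  n_down <- vapply(uk, function(k)
    sum(key == k & records$significant & records$direction == "down"), 0L)
  ratio <- ifelse(n_down > 0, n_up / n_down,
                  ifelse(n_up > 0, Inf, NaN))
  dominance <- pmax(ratio, 1 / ratio)
  highlight <- !is.nan(ratio) & dominance > ratio_threshold
  data.frame(tissue = info$tissue, cell_type = info$cell_type,
             n_up = as.integer(n_up), n_down = as.integer(n_down),
             ratio = ratio, highlight = highlight,
             row.names = NULL, stringsAsFactors = FALSE)
}

# classify a vector of per-age means by signs of consecutive differences
.classify_means <- function(means, eps) {
  d <- diff(means)
  if (all(d >= eps)) return("monotonic_up")
  if (all(d <= -eps)) return("monotonic_down")
  k <- length(d)
  for (j in seq_len(k - 1)) {
    if (all(d[1:j] >= eps) && all(d[(j + 1):k] <= -eps))
      return("up_then_down")
    if (all(d[1:j] <= -eps) && all(d[(j + 1):k] >= eps))
      return("down_then_up")
  }
  "flat"
}

#' Classify a gene's expression trajectory over age
#'
#' Computes the mean log-normalized expression at each requested age and
#' classifies the sign pattern of consecutive differences with tolerance
#' `eps`: all rises give `monotonic_up`, all falls `monotonic_down`, a
#' rise followed by a fall `up_then_down`, the reverse `down_then_up`,
#' anything else `flat`.
#'
#' @param atlas A preprocessed [expression_atlas()].
#' @param tissue,cell_type Group identifiers.
#' @param gene Gene identifier.
#' @param ages Ages (months) at which means are taken; defaults to the
#'   ages present in the group, sorted.
#' @param eps Tolerance in log units below which a difference is treated
#'   as no change (default 0.01).
#' @return Data frame row with the group, gene, per-age means (as a list
#'   column `means`), and `class`.
#' @export
classify_trajectory <- function(atlas, tissue, cell_type, gene,
                                ages = NULL, eps = 0.01) {
  if (is.null(atlas$lognorm))
    stop("atlas has no log-normalized layer; run preprocess() first")
  cells <- atlas$cells
  in_group <- cells$tissue == tissue & cells$cell_type == cell_type
  if (!any(in_group)) stop("group '", group_key(tissue, cell_type),
                           "' is absent from the atlas")
  if (is.null(ages)) ages <- sort(unique(cells$age_months[in_group]))
  if (length(ages) < 2) stop("at least 2 ages are required")
  gi <- match(gene, atlas$genes)
  if (is.na(gi)) stop("gene '", gene, "' is absent from the atlas")
  expr <- as.numeric(atlas$lognorm[in_group, gi])
  age <- cells$age_months[in_group]
  missing_ages <- ages[!ages %in% age]
  if (length(missing_ages) > 0)
    stop("no cells at age(s): ", paste(missing_ages, collapse = ", "))
  means <- vapply(ages, function(a) mean(expr[age == a]), 0)
  out <- data.frame(tissue = tissue, cell_type = cell_type, gene = gene,
                    class = .classify_means(means, eps),
                    stringsAsFactors = FALSE)
  out$means <- list(stats::setNames(means, ages))
  out
}
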