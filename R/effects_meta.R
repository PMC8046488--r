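#' Centered fixed-effect model for GAG score effects
#'
#' Models a cell's score as linear in age (months), sex (male = 1) and
#' one indicator per tissue-cell type, with no intercept. Response and
#' every design column are centered; the centered indicators then sum to
#' the zero vector, so the design is exactly rank-deficient by one and
#' the coefficients are taken as the minimum-norm least-squares solution
#' (via the SVD pseudo-inverse). Under that convention the tissue-cell
#' effects sum to zero and are read as deviations from the grand mean.
#' Standard errors come from the pseudo-inverse-based covariance with the
#' residual variance on `n - rank - 1` degrees of freedom; they are
#' conditional on this identification choice.
#'
#' @param scores Data frame with a `score` column; annotation columns
#'   (`age_months`, `sex`, `tissue`, `cell_type`) are taken from `scores`
#'   itself or merged from `annotations` by `cell_id`.
#' @param annotations Optional cell annotation table (e.g.
#'   `atlas$cells`).
#' @param variant `"main"` (default) or `"interaction"` (adds age x
#'   tissue-cell type columns).
#' @param old_only If `TRUE`, restrict the fit to cells with
#'   `age_months` in `old_ages` (robustness variant).
#' @param old_ages Ages defining old cells (default 18 and 24 months).
#' @return Object of class `gag_effects` with `coefficients`, `se`,
#'   `ci_low`/`ci_high` (estimate +/- 1.96 se), `p` (two-sided normal),
#'   `r_squared`, `n_cells`, `rank`, `model_variant`, `groups`,
#'   `n_per_group`.
#' @export
fit_score_effects <- function(scores, annotations = NULL,
                              variant = c("main", "interaction"),
                              old_only = FALSE, old_ages = c(18, 24)) {
  variant <- match.arg(variant)
  need <- c("age_months", "sex", "tissue", "cell_type")
  if (!all(need %in% names(scores))) {
    if (is.null(annotations))
      stop("scores lack annotation columns and no annotations were given")
    scores <- merge(scores, annotations[, c("cell_id", need)],
                    by = "cell_id", sort = FALSE)
  }
  scores <- scores[!is.na(scores$score), , drop = FALSE]
  if (old_only)
    scores <- scores[scores$age_months %in% old_ages, , drop = FALSE]
  n <- nrow(scores)
  if (n < 3) stop("fewer than 3 cells with defined scores")
  if (length(unique(scores$age_months)) < 2)
    stop("age is constant; the age effect is not identifiable")
  key <- group_key(scores$tissue, scores$cell_type)
  keys <- sort(unique(key))
  if (length(keys) < 2) stop("at least 2 tissue-cell types are required")
  Z <- outer(key, keys, "==") * 1
  colnames(Z) <- keys
  X <- cbind(age = scores$age_months,
             sex = as.numeric(scores$sex == "male"), Z)
  if (variant == "interaction") {
    AZ <- Z * scores$age_months
    colnames(AZ) <- paste0("age:", keys)
    X <- cbind(X, AZ)
  }
  y <- scores$score - mean(scores$score)
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc)
  tol <- max(sv$d) * 1e-8
  pos <- sv$d > tol
  r <- sum(pos)
  Uy <- crossprod(sv$u[, pos, drop = FALSE], y)
  beta <- drop(sv$v[, pos, drop = FALSE] %*% (Uy / sv$d[pos]))
  names(beta) <- colnames(X)
  fitted <- drop(Xc %*% beta)
  rss <- sum((y - fitted)^2)
  df_res <- n - r - 1
  sigma2 <- rss / df_res
  Vp <- sv$v[, pos, drop = FALSE]
  covb <- sigma2 * Vp %*% (t(Vp) / sv$d[pos]^2)
  se <- sqrt(pmax(diag(covb), 0))
  names(se) <- names(beta)
  p <- 2 * pnorm(-abs(beta / se))
  structure(list(
    coefficients = beta, se = se,
    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se, p = p,
    r_squared = 1 - rss / sum(y^2),
    n_cells = n, rank = r, df_residual = df_res, sigma2 = sigma2,
    model_variant = variant, groups = keys,
    n_per_group = as.integer(table(factor(key, levels = keys)))
  ), class = "gag_effects")
}

#' @export
coef.gag_effects <- function(object, ...) object$coefficients

#' @export
print.gag_effects <- function(x, ...) {
  cat("GAG score effect model (", x$model_variant, " variant), ",
      x$n_cells, " cells, ", length(x$groups), " tissue-cell types\n",
      sep = "")
  cat(sprintf("  age effect: %.4g (se %.3g, p %.3g) score units/month\n",
              x$coefficients["age"], x$se["age"], x$p["age"]))
  cat(sprintf("  sex effect (male): %.4g (se %.3g)\n",
              x$coefficients["sex"], x$se["sex"]))
  cat(sprintf("  R-squared: %.3f\n", x$r_squared))
  invisible(x)
}

#' @export
summary.gag_effects <- function(object, ...) {
  data.frame(term = names(object$coefficients),
             estimate = unname(object$coefficients),
             se = unname(object$se),
             ci_low = unname(object$ci_low),
             ci_high = unname(object$ci_high),
             p = unname(object$p),
             row.names = NULL, stringsAsFactors = FALSE)
}

# vectorized DerSimonian-Laird over columns of Y/SE matrices (NAs allowed)
.dl_meta <- function(Y, SE) {
  ok <- !is.na(Y) & !is.na(SE)
  Yz <- ifelse(ok, Y, 0)
  w <- ifelse(ok, 1 / SE^2, 0)
  K <- colSums(ok)
  sw <- colSums(w)
  ybar <- colSums(w * Yz) / sw
  Q <- colSums(w * (Yz - rep(ybar, each = nrow(Y)))^2 * ok)
  Cden <- sw - colSums(w^2) / sw
  tau2 <- ifelse(K > 1 & Cden > 0, pmax(0, (Q - (K - 1)) / Cden), 0)
  ws <- ifelse(ok, 1 / (SE^2 + rep(tau2, each = nrow(Y))), 0)
  sws <- colSums(ws)
  est <- colSums(ws * Yz) / sws
  se <- sqrt(1 / sws)
  list(estimate = est, se = se, tau2 = tau2, Q = Q, K = K)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools per-group estimates allowing between-group variance: with fixed
#' weights `w = 1/se^2` and heterogeneity `Q = sum w (y - ybar_F)^2`, the
#' moment estimator is
#' `tau2 = max(0, (Q - (K - 1)) / (sum w - sum w^2 / sum w))`; the pooled
#' estimate uses re-weights `1 / (se^2 + tau2)`. With a single input the
#' estimate is returned unchanged with `tau2 = 0`.
#'
#' @param y Numeric vector of estimates (or a 2-column data frame /
#'   matrix of estimate, se).
#' @param se Standard errors (all > 0).
#' @return Object of class `meta_estimate` with `estimate`, `se`, `tau2`,
#'   `Q`, `K`, `ci_low`, `ci_high`, `p` (two-sided normal).
#' @examples
#' meta_random_effects(c(0.01, 0.03), c(0.01, 0.01))
#' @export
meta_random_effects <- function(y, se = NULL) {
  if (is.null(se)) {
    y <- as.data.frame(y)
    se <- y[[2]]; y <- y[[1]]
  }
  if (length(y) == 0) stop("at least one estimate is required")
  if (length(y) != length(se)) stop("y and se lengths differ")
  if (any(!is.finite(se)) || any(se <= 0))
    stop("all standard errors must be positive and finite")
  r <- .dl_meta(matrix(y, ncol = 1), matrix(se, ncol = 1))
  est <- r$estimate[1]; pse <- r$se[1]
  structure(list(estimate = est, se = pse, tau2 = r$tau2[1], Q = r$Q[1],
                 K = length(y), ci_low = est - 1.96 * pse,
                 ci_high = est + 1.96 * pse,
                 p = 2 * pnorm(-abs(est / pse))),
            class = "meta_estimate")
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf(
    "random-effects meta-analysis (DL): %.4g [%.4g, %.4g], K = %d, tau2 = %.3g, Q = %.3g, p = %.3g\n",
    x$estimate, x$ci_low, x$ci_high, x$K, x$tau2, x$Q, x$p))
  invisible(x)
}

#' Meta-analyzed score effects per cell category with pairwise contrasts
#'
#' Pools the tissue-cell-type coefficients of a fitted [fit_score_effects()]
#' model within each level of a grouping label (functional category or
#' lifespan label), using random-effects meta-analysis, and compares every
#' pair of levels with a two-sided normal z-test
#' `z = (m1 - m2) / sqrt(se1^2 + se2^2)`. Tissue-cell types without a
#' label are excluded (their count is reported in attribute
#' `"n_unlabeled"`).
#'
#' @param effects A `gag_effects` object.
#' @param group_info Data frame mapping tissue-cell types to labels, as
#'   produced by [eligible_groups()] (columns `group` and the label
#'   column).
#' @param grouping Name of the label column, e.g. `"functional_category"`
#'   or `"lifespan_label"`.
#' @return List of class `group_contrast`: `$meta` (one row per label:
#'   estimate, se, ci, tau2, Q, K, p) and `$contrasts` (pairwise z-tests).
#' @export
group_contrast <- function(effects, group_info,
                           grouping = "functional_category") {
  stopifnot(inherits(effects, "gag_effects"))
  if (!grouping %in% names(group_info))
    stop("grouping column '", grouping, "' not found")
  keys <- effects$groups
  est <- effects$coefficients[keys]
  se <- effects$se[keys]
  lab <- group_info[[grouping]][match(keys, group_info$group)]
  n_unlabeled <- sum(is.na(lab))
  keep <- !is.na(lab)
  labs <- sort(unique(lab[keep]))
  meta <- do.call(rbind, lapply(labs, function(l) {
    i <- keep & lab == l
    m <- meta_random_effects(est[i], se[i])
    data.frame(label = l, estimate = m$estimate, se = m$se,
               ci_low = m$ci_low, ci_high = m$ci_high, tau2 = m$tau2,
               Q = m$Q, K = m$K, p = m$p, stringsAsFactors = FALSE)
  }))
  contrasts <- NULL
  if (length(labs) >= 2) {
    pairs <- combn(labs, 2)
    contrasts <- do.call(rbind, apply(pairs, 2, function(pr) {
      a <- meta[meta$label == pr[1], ]; b <- meta[meta$label == pr[2], ]
      z <- (a$estimate - b$estimate) / sqrt(a$se^2 + b$se^2)
      data.frame(label_a = pr[1], label_b = pr[2],
                 diff = a$estimate - b$estimate, z = z,
                 p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
    }))
  }
  structure(list(meta = meta, contrasts = contrasts,
                 grouping = grouping),
            class = "group_contrast", n_unlabeled = n_unlabeled)
}

#' @export
print.group_contrast <- function(x, ...) {
  cat("meta-analyzed score effects by", x$grouping, "\n")
  print(x$meta, row.names = FALSE)
  if (!is.null(x$contrasts)) {
    cat("pairwise contrasts:\n")
    print(x$contrasts, row.names = FALSE)
  }
  invisible(x)
}

#' Compare tissue-cell-type score effects between two fitted models
#'
#' Pearson correlation of the shared tissue-cell-type coefficients of two
#' [fit_score_effects()] fits (e.g. two datasets scored with the same GAG
#' set), with its two-sided p-value.
#'
#' @param model_a,model_b `gag_effects` objects.
#' @return List with `r`, `p`, `n_shared` and the matched `groups`.
#' @export
compare_effects <- function(model_a, model_b) {
  ga <- setdiff(model_a$groups, NA)
  shared <- intersect(ga, model_b$groups)
  if (length(shared) < 3)
    stop("fewer than 3 shared tissue-cell types (", length(shared), ")")
  a <- model_a$coefficients[shared]
  b <- model_b$coefficients[shared]
  ct <- suppressWarnings(cor.test(a, b, method = "pearson"))
  list(r = unname(ct$estimate), p = ct$p.value,
       n_shared = length(shared), groups = shared)
}
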