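#' Default tissue layout for simulated atlases
#'
#' Three tissues with two, two and one cell types, each cell type carrying
#' a functional category and a lifespan label. The functional categories
#' (immune, stem, endothelial) are assigned so that no single category
#' exceeds 50% of the tissue-weighted groups; category-specific genes
#' planted under this layout therefore cannot be selected as global aging
#' genes, giving clean ground truth for the category-specific stage.
#'
#' @return A list of tissue specifications, each a list with elements
#'   `name`, `cell_types`, `categories` and `lifespan`.
#' @export
default_tissues <- function() {
  list(
    list(name = "T1", cell_types = c("ct1", "ct2"),
         categories = c("immune", "stem"), lifespan = c("short", "long")),
    list(name = "T2", cell_types = c("ct3", "ct4"),
         categories = c("immune", "endothelial"), lifespan = c("short", "long")),
    list(name = "T3", cell_types = "ct5",
         categories = "stem", lifespan = "long")
  )
}

#' Configuration for the synthetic atlas generator
#'
#' Defines the study design emulated by [simulate_atlas()]: a multi-tissue
#' atlas with cells at ages 3, 18 and 24 months, two sexes, and a minority
#' of genes carrying planted log-linear age effects. Gene classes are
#' global up/down (direction-consistent effect in every tissue-cell type),
#' category-specific (effect only in cell types of one functional
#' category) and null. Counts are negative binomial with per-cell depth
#' variation, so zero counts occur and the preprocessing filters are
#' exercised.
#'
#' Default effect sizes and design follow the deep-coverage plate-sorted
#' (Smart-seq2 like) regime: per-gene baselines of `exp(2.5)` to
#' `exp(4.5)` expected counts, mild overdispersion (0.05) and a planted
#' global effect of 0.01 natural-log fold change per month — the smallest
#' effect the downstream selection treats as biologically meaningful.
#'
#' @param tissues List of tissue specs as produced by [default_tissues()].
#' @param ages_months Numeric ages at which cells are sampled (>= 2 values).
#' @param cells_per_type_per_age Cells simulated per cell type and age.
#' @param n_genes Total number of genes.
#' @param frac_global_up,frac_global_down,frac_category_specific
#'   Fractions of genes in each planted class; the remainder is null.
#' @param beta_global Planted global age effect, natural-log fold change
#'   per month (positive for up genes, negated for down genes).
#' @param beta_category Planted age effect for category-specific genes
#'   inside their designated category (exactly 0 elsewhere).
#' @param sex_effect_sd Standard deviation of per-gene sex effects
#'   (male = 1 coding) on the log mean.
#' @param baseline_logmean_range Interval for per-gene baseline natural-log
#'   mean counts.
#' @param depth_lognormal_params `c(mu, sigma)` of the per-cell log-normal
#'   depth multiplier.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param seed Integer seed; identical seeds give identical atlases.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(tissues = default_tissues(),
                              ages_months = c(3, 18, 24),
                              cells_per_type_per_age = 150L,
                              n_genes = 2000L,
                              frac_global_up = 0.0125,
                              frac_global_down = 0.0125,
                              frac_category_specific = 0.025,
                              beta_global = 0.01,
                              beta_category = 0.01,
                              sex_effect_sd = 0.05,
                              baseline_logmean_range = c(2.5, 4.5),
                              depth_lognormal_params = c(mu = 0, sigma = 0.25),
                              nb_dispersion = 0.05,
                              seed = 1L) {
  if (length(tissues) == 0L)
    stop("configuration error: at least one tissue is required")
  for (ts in tissues) {
    if (is.null(ts$name) || length(ts$cell_types) == 0L)
      stop("configuration error: every tissue needs a name and >= 1 cell type")
  }
  fracs <- c(frac_global_up, frac_global_down, frac_category_specific)
  if (any(fracs < 0) || sum(fracs) > 1)
    stop("configuration error: gene-class fractions must be non-negative and sum to <= 1")
  if (cells_per_type_per_age < 1)
    stop("configuration error: cells_per_type_per_age must be >= 1")
  if (length(unique(ages_months)) < 2)
    stop("configuration error: at least 2 distinct ages are required")
  if (nb_dispersion < 0) stop("configuration error: nb_dispersion must be >= 0")
  if (length(baseline_logmean_range) != 2 || diff(baseline_logmean_range) < 0)
    stop("configuration error: baseline_logmean_range must be an increasing interval")
  structure(list(
    tissues = tissues,
    ages_months = sort(unique(ages_months)),
    cells_per_type_per_age = as.integer(cells_per_type_per_age),
    n_genes = as.integer(n_genes),
    frac_global_up = frac_global_up,
    frac_global_down = frac_global_down,
    frac_category_specific = frac_category_specific,
    frac_null = 1 - sum(fracs),
    beta_global = beta_global,
    beta_category = beta_category,
    sex_effect_sd = sex_effect_sd,
    baseline_logmean_range = baseline_logmean_range,
    depth_lognormal_params = depth_lognormal_params,
    nb_dispersion = nb_dispersion,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# flat (tissue, cell_type, category, lifespan) table from a tissue spec list
.group_table <- function(tissues) {
  do.call(rbind, lapply(tissues, function(ts) {
    k <- length(ts$cell_types)
    data.frame(
      tissue = rep(ts$name, k),
      cell_type = ts$cell_types,
      functional_category = (ts$categories %||% rep(NA_character_, k)),
      lifespan_label = (ts$lifespan %||% rep(NA_character_, k)),
      stringsAsFactors = FALSE
    )
  }))
}

#' Simulate a multi-tissue aging expression atlas with known ground truth
#'
#' Draws a cells x genes count matrix under a negative-binomial model with
#' log mean `baseline_g + beta_gc * age_i + gamma_g * sex_i + log(depth_i)`,
#' where `beta_gc` encodes the planted gene class (global up/down,
#' category-specific, or null), `gamma_g` is a per-gene sex effect
#' (male = 1), and `depth_i` is a log-normal per-cell depth multiplier.
#'
#' @param config A [simulation_config()].
#' @return A list with components `atlas` (an [expression_atlas()] of raw
#'   counts plus cell/gene annotations) and `truth` (a `ground_truth`
#'   list: `gene_classes` data frame, `beta` group x gene matrix of true
#'   age effects, `sex_effects` per-gene vector).
#' @examples
#' sim <- simulate_atlas(simulation_config(cells_per_type_per_age = 10,
#'                                         n_genes = 50))
#' table(sim$truth$gene_classes$class)
#' @export
simulate_atlas <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  groups <- .group_table(config$tissues)
  n_groups <- nrow(groups)
  ages <- config$ages_months
  m <- config$cells_per_type_per_age
  n_cells <- n_groups * length(ages) * m

  # cell annotations: balanced sexes within each (cell type, age) block
  gidx <- rep(seq_len(n_groups), each = length(ages) * m)
  age <- rep(rep(ages, each = m), times = n_groups)
  sex <- rep_len(c("female", "male"), n_cells)
  cells <- data.frame(
    cell_id = sprintf("cell%06d", seq_len(n_cells)),
    age_months = age,
    sex = sex,
    tissue = groups$tissue[gidx],
    cell_type = groups$cell_type[gidx],
    functional_category = groups$functional_category[gidx],
    lifespan_label = groups$lifespan_label[gidx],
    stringsAsFactors = FALSE
  )

  # gene classes: counts are the rounded configured fractions
  G <- config$n_genes
  n_up <- round(config$frac_global_up * G)
  n_down <- round(config$frac_global_down * G)
  n_cat <- round(config$frac_category_specific * G)
  cats <- unique(groups$functional_category)
  cats <- cats[!is.na(cats)]
  if (n_cat > 0 && length(cats) == 0L)
    stop("configuration error: category-specific genes require functional categories")
  gene_ids <- sprintf("g%04d", seq_len(G))
  cls <- rep("null", G)
  gene_cat <- rep(NA_character_, G)
  if (n_up > 0) cls[seq_len(n_up)] <- "global_up"
  if (n_down > 0) cls[n_up + seq_len(n_down)] <- "global_down"
  if (n_cat > 0) {
    gene_cat[n_up + n_down + seq_len(n_cat)] <- rep_len(cats, n_cat)
    cls[n_up + n_down + seq_len(n_cat)] <-
      paste0("category_specific:", gene_cat[n_up + n_down + seq_len(n_cat)])
  }

  # true age-effect matrix, groups x genes
  beta <- matrix(0, n_groups, G,
                 dimnames = list(group_key(groups$tissue, groups$cell_type),
                                 gene_ids))
  beta[, cls == "global_up"] <- config$beta_global
  beta[, cls == "global_down"] <- -config$beta_global
  for (j in which(!is.na(gene_cat)))
    beta[groups$functional_category %in% gene_cat[j], j] <- config$beta_category

  baseline <- runif(G, config$baseline_logmean_range[1],
                    config$baseline_logmean_range[2])
  gamma <- rnorm(G, 0, config$sex_effect_sd)
  dlp <- config$depth_lognormal_params
  depth <- exp(rnorm(n_cells, dlp[1], dlp[2]))
  sex01 <- as.numeric(cells$sex == "male")

  eta <- beta[gidx, , drop = FALSE] * age          # rows recycle over cells
  eta <- sweep(eta, 2L, baseline, "+")
  eta <- eta + outer(sex01, gamma)
  eta <- eta + log(depth)
  mu <- exp(eta)
  counts <- if (config$nb_dispersion == 0) {
    matrix(rpois(length(mu), mu), n_cells, G)
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
           n_cells, G)
  }
  dimnames(counts) <- list(cells$cell_id, gene_ids)

  atlas <- expression_atlas(Matrix(counts, sparse = TRUE), cells, gene_ids)
  truth <- structure(list(
    gene_classes = data.frame(gene = gene_ids, class = cls,
                              category = gene_cat,
                              sex_effect = gamma,
                              baseline_logmean = baseline,
                              stringsAsFactors = FALSE),
    beta = beta,
    sex_effects = stats::setNames(gamma, gene_ids)
  ), class = "ground_truth")
  list(atlas = atlas, truth = truth)
}

#' Simulate per-cell aging scores with known linear effects
#'
#' Generates a cell table whose score is
#' `beta_age * age + beta_sex * sex + group effect + N(0, noise_sd)`,
#' for parameter-recovery tests of [fit_score_effects()].
#'
#' @param effects List with `beta_age`, `beta_sex`, `group_effects` (named
#'   numeric vector, names are `tissue|cell_type` keys) and optionally
#'   `ages` (default `c(3, 18, 24)`).
#' @param n_cells_per_type Cells per tissue-cell type (ages and sexes
#'   cycled within each).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Data frame with `cell_id`, `age_months`, `sex`, `tissue`,
#'   `cell_type`, `score`; the generating effects are attached as
#'   attribute `"truth"`.
#' @export
simulate_scores <- function(effects, n_cells_per_type = 200L, noise_sd = 1,
                            seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(is.numeric(effects$beta_age), is.numeric(effects$beta_sex),
            length(effects$group_effects) >= 1,
            !is.null(names(effects$group_effects)))
  set.seed(seed)
  ages <- effects$ages %||% c(3, 18, 24)
  keys <- names(effects$group_effects)
  parts <- strsplit(keys, "|", fixed = TRUE)
  tissue <- vapply(parts, function(p) p[1], "")
  cell_type <- vapply(parts, function(p) if (length(p) > 1) p[2] else p[1], "")
  K <- length(keys)
  n <- K * n_cells_per_type
  g <- rep(seq_len(K), each = n_cells_per_type)
  age <- rep(rep_len(ages, n_cells_per_type), times = K)
  sex01 <- rep(rep_len(c(0, 1), n_cells_per_type), times = K)
  score <- effects$beta_age * age + effects$beta_sex * sex01 +
    effects$group_effects[g] + rnorm(n, 0, noise_sd)
  out <- data.frame(
    cell_id = sprintf("sc%06d", seq_len(n)),
    age_months = age,
    sex = ifelse(sex01 == 1, "male", "female"),
    tissue = tissue[g],
    cell_type = cell_type[g],
    score = as.numeric(score),
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- effects
  out
}
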