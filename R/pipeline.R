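#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: an input (a
#' [simulation_config()] or paths to an on-disk atlas), a preprocessing
#' preset, analysis thresholds, the grouping column for meta-analysis,
#' the output directory and the seed. Presets fix the filter defaults
#' exactly as in [preprocess()] / [eligible_groups()]: `facs` (min 100
#' cells per age side), `droplet` (min 500), `bulk`.
#'
#' @param simulation A [simulation_config()], or `NULL` when loading from
#'   disk.
#' @param atlas_paths Named list with `counts`, `cells`, `genes` paths
#'   (used when `simulation` is `NULL`).
#' @param preset Preprocessing preset: `"facs"`, `"droplet"` or `"bulk"`.
#' @param out_dir Output directory for stage TSVs and the manifest.
#' @param fdr,beta Differential-expression thresholds.
#' @param gag_sig,gag_direction GAG selection thresholds.
#' @param grouping Label column for meta-analysis and specific-gene sets.
#' @param young_ages,old_ages Age sets for eligibility.
#' @param min_cells Override for the eligibility cell minimum (`NULL` =
#'   preset default).
#' @param seed Integer seed (re-seeds the simulation when given).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            atlas_paths = NULL,
                            preset = c("facs", "droplet", "bulk"),
                            out_dir = tempfile("gagatlas_run_"),
                            fdr = 0.01, beta = 0.005,
                            gag_sig = 0.5, gag_direction = 0.8,
                            grouping = "functional_category",
                            young_ages = 3, old_ages = c(18, 24),
                            min_cells = NULL, seed = NULL) {
  preset <- match.arg(preset)
  if (is.null(simulation) && is.null(atlas_paths))
    stop("either a simulation config or atlas paths are required")
  if (!is.null(seed) && !is.null(simulation)) simulation$seed <- as.integer(seed)
  structure(list(
    simulation = simulation, atlas_paths = atlas_paths, preset = preset,
    out_dir = out_dir, fdr = fdr, beta = beta, gag_sig = gag_sig,
    gag_direction = gag_direction, grouping = grouping,
    young_ages = young_ages, old_ages = old_ages,
    min_cells = min_cells %||% switch(preset, facs = 100, droplet = 500,
                                      bulk = 1),
    seed = seed %||% (if (!is.null(simulation)) simulation$seed else NA)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulation:` block mirrors [simulation_config()] (its `tissues:` is a
#' list of `name` / `cell_types` / `categories` / `lifespan` entries).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    sa <- y$simulation
    if (!is.null(sa$baseline_logmean_range))
      sa$baseline_logmean_range <- as.numeric(sa$baseline_logmean_range)
    if (!is.null(sa$depth_lognormal_params))
      sa$depth_lognormal_params <- as.numeric(sa$depth_lognormal_params)
    sim <- do.call(simulation_config, sa)
  }
  args <- y[setdiff(names(y), "simulation")]
  args$simulation <- sim
  do.call(pipeline_config, args)
}

# stable short hash of the configuration (djb2 over its deparsed form)
config_hash <- function(config) {
  x <- config[setdiff(names(config), "out_dir")]
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(x)
}

#' Run the full aging-signature pipeline
#'
#' Executes simulate/load, preprocess, eligibility, differential
#' expression, GAG selection, GAG scoring, the score effect model with
#' category meta-analysis, and category-specific gene discovery, writing
#' one TSV per stage plus a JSON manifest into the output directory.
#' Outputs are pure functions of the configuration, so a rerun with the
#' same seed reproduces them byte for byte. A failing stage aborts with
#' the stage name; TSVs already written are left in place.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the output directory, the in-memory
#'   stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); warns <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  atlas <- stage("input", {
    if (!is.null(config$simulation)) {
      sim <- simulate_atlas(config$simulation)
      truth <- sim$truth
      sim$atlas
    } else {
      load_atlas(config$atlas_paths$counts, config$atlas_paths$cells,
                 config$atlas_paths$genes)
    }
  })

  atlas <- stage("preprocess", preprocess(atlas, preset = config$preset))
  groups <- stage("eligible_groups",
    eligible_groups(atlas, config$young_ages, config$old_ages,
                    min_cells = config$min_cells))
  rows$groups <- .write_tsv(groups, file.path(config$out_dir, "groups.tsv"))

  records <- stage("dge",
    run_dge(atlas, groups, fdr_threshold = config$fdr,
            beta_threshold = config$beta))
  warns$dge_genes_skipped <- attr(records, "n_skipped")
  rows$dge <- .write_tsv(records, file.path(config$out_dir, "dge.tsv"))
  ud <- updown_summary(records)
  rows$updown <- .write_tsv(ud, file.path(config$out_dir, "updown.tsv"))

  gag_table <- stage("global_genes",
    weighted_proportions(records, groups, sig_threshold = config$gag_sig,
                         direction_threshold = config$gag_direction))
  gags <- select_gags(gag_table, sig_threshold = config$gag_sig,
                      direction_threshold = config$gag_direction)
  rows$gag_table <- .write_tsv(gags$table,
                               file.path(config$out_dir, "gag_table.tsv"))
  gag_sets <- data.frame(
    gene = c(gags$global_up, gags$global_down, gags$global_mixed),
    class = rep(c("global_up", "global_down", "global_mixed"),
                c(length(gags$global_up), length(gags$global_down),
                  length(gags$global_mixed))),
    stringsAsFactors = FALSE)
  rows$gag_sets <- .write_tsv(gag_sets,
                              file.path(config$out_dir, "gag_sets.tsv"))

  effects <- contrasts <- NULL
  if (length(gags$global_up) > 0 && length(gags$global_down) > 0) {
    scores <- stage("gag_score",
      compute_gag_score(atlas, gags$global_up, gags$global_down))
    warns$undefined_scores <- sum(scores$undefined)
    rows$gag_scores <- .write_tsv(scores,
      file.path(config$out_dir, "gag_scores.tsv"))
    effects <- stage("effects",
      fit_score_effects(scores, annotations = atlas$cells))
    rows$effects <- .write_tsv(summary(effects),
      file.path(config$out_dir, "effects.tsv"))
    if (config$grouping %in% names(groups) &&
        length(unique(stats::na.omit(groups[[config$grouping]]))) >= 2) {
      contrasts <- stage("meta", group_contrast(effects, groups,
                                                grouping = config$grouping))
      rows$meta_groups <- .write_tsv(contrasts$meta,
        file.path(config$out_dir, "meta_groups.tsv"))
      rows$contrasts <- .write_tsv(contrasts$contrasts,
        file.path(config$out_dir, "contrasts.tsv"))
    }
  } else {
    scores <- NULL
    warns$score_stage_skipped <- "no up- or no down-GAGs selected"
  }

  specific <- NULL
  if (length(unique(stats::na.omit(groups$functional_category))) >= 2) {
    specific <- stage("category_specific",
      find_specific_genes(records, groups, level = "category",
                          fdr = config$fdr, beta_threshold = config$beta))
    rows$specific_genes <- .write_tsv(specific,
      file.path(config$out_dir, "specific_genes.tsv"))
  }

  manifest <- list(
    package = "gagatlas",
    version = as.character(packageVersion("gagatlas")),
    config_hash = config_hash(config),
    preset = config$preset,
    seed = config$seed,
    thresholds = list(fdr = config$fdr, beta = config$beta,
                      gag_sig = config$gag_sig,
                      gag_direction = config$gag_direction),
    rows = rows, warnings = warns
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = config$out_dir, atlas = atlas, truth = truth,
                 groups = groups, records = records, updown = ud,
                 gag_table = gag_table, gags = gags,
                 scores = scores, effects = effects,
                 contrasts = contrasts, specific = specific,
                 manifest = manifest))
}
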