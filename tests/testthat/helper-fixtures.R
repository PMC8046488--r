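# shared fixture builders; all data is generated in code at test time

null_config <- function(seed, n_genes = 2000, cells = 150, ...) {
  simulation_config(frac_global_up = 0, frac_global_down = 0,
                    frac_category_specific = 0, n_genes = n_genes,
                    cells_per_type_per_age = cells, seed = seed, ...)
}

tiny_sim <- function(seed = 1, cells = 10, n_genes = 50, ...) {
  simulate_atlas(simulation_config(cells_per_type_per_age = cells,
                                   n_genes = n_genes, seed = seed, ...))
}

# hand-built DGE record table for aggregation tests
make_records <- function(tissue, cell_type, gene, beta, se = 0.001,
                         significant = TRUE) {
  data.frame(tissue = tissue, cell_type = cell_type, gene = gene,
             beta_age = beta, se_age = se,
             p_age = 2 * pnorm(-abs(beta / se)),
             q_age = 2 * pnorm(-abs(beta / se)),
             beta_sex = 0, n_cells = 200L,
             significant = significant,
             direction = ifelse(beta > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

make_groups <- function(tissue, cell_type, weight,
                        functional_category = NA_character_,
                        lifespan_label = NA_character_) {
  data.frame(tissue = tissue, cell_type = cell_type,
             group = paste(tissue, cell_type, sep = "|"),
             n_young = 150L, n_old = 300L, n_cells = 450L,
             weight = weight, functional_category = functional_category,
             lifespan_label = lifespan_label, stringsAsFactors = FALSE)
}

# minimal atlas with a lognorm layer set directly (counts are a stand-in)
manual_lognorm_atlas <- function(lognorm, ages = NULL, sexes = NULL) {
  n <- nrow(lognorm)
  cells <- data.frame(
    cell_id = sprintf("c%03d", seq_len(n)),
    age_months = ages %||% rep_len(c(3, 18, 24), n),
    sex = sexes %||% rep_len(c("female", "male"), n),
    tissue = "T", cell_type = "ct", stringsAsFactors = FALSE)
  genes <- sprintf("g%02d", seq_len(ncol(lognorm)))
  at <- expression_atlas(Matrix::Matrix(round(exp(lognorm)),
                                        sparse = TRUE),
                         cells, genes)
  at$lognorm <- Matrix::Matrix(lognorm, sparse = TRUE,
                               dimnames = list(cells$cell_id, genes))
  at
}

`%||%` <- function(a, b) if (is.null(a)) b else a
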