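test_that("an atlas written to disk round-trips to an equal atlas", {
  sim <- tiny_sim(seed = 1)
  dir <- withr::local_tempdir()
  write_atlas(sim$atlas, dir)
  back <- load_atlas(file.path(dir, "counts.mtx"),
                     file.path(dir, "cells.tsv"),
                     file.path(dir, "genes.tsv"))
  expect_equal(as.matrix(back$counts), as.matrix(sim$atlas$counts))
  expect_equal(back$cells$cell_id, sim$atlas$cells$cell_id)
  expect_equal(back$cells$age_months, sim$atlas$cells$age_months)
  expect_identical(back$genes, sim$atlas$genes)
})

test_that("malformed inputs are rejected with informative errors", {
  sim <- tiny_sim(seed = 1)
  dir <- withr::local_tempdir()
  write_atlas(sim$atlas, dir)
  # cell table one row short of the matrix
  cells <- read.delim(file.path(dir, "cells.tsv"))
  write.table(cells[-1, ], file.path(dir, "cells_bad.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(load_atlas(file.path(dir, "counts.mtx"),
                          file.path(dir, "cells_bad.tsv"),
                          file.path(dir, "genes.tsv")),
               "dimension mismatch")
  # negative count names the offending cell and gene
  cnt <- as.matrix(sim$atlas$counts)
  cnt[2, 3] <- -1
  expect_error(expression_atlas(cnt, sim$atlas$cells, sim$atlas$genes),
               "negative count.*cell000002.*g0003")
  # missing required annotation column
  expect_error(expression_atlas(sim$atlas$counts,
                                sim$atlas$cells[, -2], sim$atlas$genes),
               "age_months")
})

test_that("the gene filter removes genes seen in fewer than 3 cells", {
  # 5 cells x 3 genes: g1 in 2 cells, g2 in 3 cells, g3 in all
  cnt <- rbind(c(1, 1, 6000), c(1, 1, 6000), c(0, 1, 6000),
               c(0, 0, 6000), c(0, 0, 6000))
  cells <- data.frame(cell_id = paste0("c", 1:5),
                      age_months = c(3, 3, 18, 24, 24),
                      sex = rep("female", 5), tissue = "T",
                      cell_type = "ct", stringsAsFactors = FALSE)
  at <- expression_atlas(cnt, cells, c("g1", "g2", "g3"))
  out <- preprocess(at, min_cells_per_gene = 3, min_genes_per_cell = 1,
                    min_counts_per_cell = 0)
  expect_identical(out$genes, c("g2", "g3"))
})

test_that("cell filters and normalization match a hand-enumerated result", {
  # cells: c1 passes; c2 too few genes; c3 too few counts
  cnt <- rbind(c(3000, 3000, 10), c(6010, 0, 0), c(100, 100, 10))
  cells <- data.frame(cell_id = paste0("c", 1:3),
                      age_months = c(3, 18, 24), sex = rep("male", 3),
                      tissue = "T", cell_type = "ct",
                      stringsAsFactors = FALSE)
  at <- expression_atlas(cnt, cells, c("g1", "g2", "g3"))
  out <- preprocess(at, min_cells_per_gene = 1, min_genes_per_cell = 2,
                    min_counts_per_cell = 1000)
  expect_identical(out$cells$cell_id, "c1")
  # normalization identity: exp(lognorm) - 1 row-sums to 1e4
  expect_equal(sum(expm1(as.matrix(out$lognorm))), 1e4,
               tolerance = 1e-9)
  expect_equal(as.numeric(out$lognorm[1, ]),
               log1p(1e4 * c(3000, 3000, 10) / 6010))
  expect_error(preprocess(at, min_cells_per_gene = 1,
                          min_genes_per_cell = 5,
                          min_counts_per_cell = 0),
               "empty result")
})

test_that("normalization identity holds for every retained cell and preprocessing is idempotent", {
  sim <- tiny_sim(seed = 6, cells = 30, n_genes = 400)
  out <- preprocess(sim$atlas, preset = "facs")
  sums <- Matrix::rowSums(expm1(out$lognorm))
  expect_true(all(abs(sums - 1e4) < 1e-6))
  again <- preprocess(out, preset = "facs")
  expect_equal(as.matrix(again$lognorm), as.matrix(out$lognorm))
  expect_identical(again$cells, out$cells)
})

test_that("eligibility uses >= min_cells on both age sides and weights sum to 1 per tissue", {
  # one group with exactly 100 young cells is eligible at min_cells = 100
  cells <- data.frame(
    cell_id = sprintf("c%04d", 1:350),
    age_months = c(rep(3, 100), rep(18, 150), rep(24, 100)),
    sex = "female", tissue = "T", cell_type = "ct",
    stringsAsFactors = FALSE)
  cnt <- matrix(1, 350, 2)
  at <- expression_atlas(cnt, cells, c("g1", "g2"))
  g <- eligible_groups(at, min_cells = 100)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_young, 100)
  expect_equal(g$n_old, 250)
  expect_equal(g$weight, 1)
  expect_equal(nrow(eligible_groups(at, min_cells = 101)), 0)
  expect_error(eligible_groups(at, young_ages = numeric(0)),
               "configuration error")

  # default layout: 3 tissues x {2, 2, 1} cell types
  sim <- simulate_atlas(simulation_config(cells_per_type_per_age = 8,
                                          n_genes = 20, seed = 2))
  gg <- eligible_groups(sim$atlas, min_cells = 8)
  expect_equal(sort(gg$weight), c(0.5, 0.5, 0.5, 0.5, 1.0))
  expect_equal(sum(gg$weight), 3)
  w_by_tissue <- tapply(gg$weight, gg$tissue, sum)
  expect_true(all(w_by_tissue == 1))
})

test_that("cell QC counts expressed genes and flags depth/age correlations", {
  cnt <- rbind(c(0, 2, 5, 0), c(0, 2, 5, 0), c(1, 1, 1, 1))
  cells <- data.frame(cell_id = c("a", "b", "c"),
                      age_months = c(3, 3, 24), sex = "male",
                      tissue = "T", cell_type = "ct",
                      stringsAsFactors = FALSE)
  at <- expression_atlas(cnt, cells, paste0("g", 1:4))
  qc <- cell_qc(at)
  expect_equal(qc$table$n_expressed_genes, c(2L, 2L, 4L))
  expect_equal(qc$table$total_counts, c(7, 7, 4))
  # duplicate cells get identical QC rows
  expect_equal(qc$table[1, -1], qc$table[2, -1], ignore_attr = TRUE)
})

test_that("under a constant-depth null the detection rate is uncorrelated with age", {
  cfg <- null_config(seed = 9, n_genes = 300, cells = 3334,
                     baseline_logmean_range = c(-2, 1),
                     nb_dispersion = 0.5,
                     depth_lognormal_params = c(0, 0),
                     tissues = list(list(name = "T", cell_types = "ct",
                                         categories = "immune",
                                         lifespan = "long")),
                     ages_months = c(3, 18, 24))
  sim <- simulate_atlas(cfg)
  qc <- cell_qc(sim$atlas)
  r <- qc$correlations$estimate[qc$correlations$pair == "cdr_vs_age" &
                                qc$correlations$method == "pearson"]
  expect_lt(abs(r), 0.05)
})
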