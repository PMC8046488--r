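test_that("a noiseless age trend is recovered with R-squared one", {
  sc <- simulate_scores(list(beta_age = 0.1, beta_sex = 0,
                             group_effects = c("T1|a" = 0, "T1|b" = 0,
                                               "T2|c" = 0)),
                        n_cells_per_type = 30, noise_sd = 0, seed = 2)
  fit <- fit_score_effects(sc)
  expect_equal(unname(coef(fit)["age"]), 0.1, tolerance = 1e-10)
  expect_equal(max(abs(coef(fit)[fit$groups])), 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("estimates are invariant to cell order and to constant score shifts", {
  sc <- simulate_scores(list(beta_age = 0.05, beta_sex = -0.2,
                             group_effects = c("T1|a" = 0.5,
                                               "T1|b" = -0.5)),
                        n_cells_per_type = 60, noise_sd = 1, seed = 3)
  fit <- fit_score_effects(sc)
  perm <- sc[sample(nrow(sc)), ]
  expect_equal(coef(fit_score_effects(perm)), coef(fit),
               tolerance = 1e-10)
  shifted <- sc; shifted$score <- shifted$score + 11.3
  expect_equal(coef(fit_score_effects(shifted)), coef(fit),
               tolerance = 1e-9)
})

test_that("the centered parameterization makes group effects sum to zero", {
  sc <- simulate_scores(list(beta_age = 0.05, beta_sex = 0.1,
                             group_effects = c("T1|a" = 0.5, "T1|b" = -0.2,
                                               "T2|c" = -0.3)),
                        n_cells_per_type = 80, noise_sd = 1, seed = 5)
  fit <- fit_score_effects(sc)
  expect_equal(sum(coef(fit)[fit$groups]), 0, tolerance = 1e-8)
  # balanced groups: the cell-weighted sum vanishes as well
  expect_equal(sum(fit$n_per_group * coef(fit)[fit$groups]), 0,
               tolerance = 1e-5)
  expect_equal(unname(fit$ci_low),
               unname(coef(fit) - 1.96 * fit$se), tolerance = 1e-12)
})

test_that("planted score effects are recovered within three standard errors", {
  truth <- list(beta_age = 0.05, beta_sex = -0.2,
                group_effects = c("T1|a" = 0.5, "T1|b" = -0.5,
                                  "T2|c" = 0.3, "T2|d" = -0.3,
                                  "T3|e" = 0))
  sc <- simulate_scores(truth, n_cells_per_type = 200, noise_sd = 1,
                        seed = 7)
  fit <- fit_score_effects(sc)
  tv <- c(age = truth$beta_age, sex = truth$beta_sex,
          truth$group_effects)
  expect_true(all(abs(coef(fit)[names(tv)] - tv) <=
                    3 * fit$se[names(tv)]))
})

test_that("degenerate effect-model inputs error", {
  sc <- simulate_scores(list(beta_age = 0, beta_sex = 0,
                             group_effects = c("T1|a" = 0, "T1|b" = 0)),
                        n_cells_per_type = 10, noise_sd = 1, seed = 1)
  const_age <- sc; const_age$age_months <- 18
  expect_error(fit_score_effects(const_age), "constant")
  expect_error(fit_score_effects(sc[1:2, ]), "3 cells")
  one_group <- sc; one_group$cell_type <- "a"; one_group$tissue <- "T1"
  expect_error(fit_score_effects(one_group), "2 tissue-cell types")
})

test_that("the interaction variant adds age-by-group terms", {
  sc <- simulate_scores(list(beta_age = 0.05, beta_sex = 0,
                             group_effects = c("T1|a" = 0.5,
                                               "T1|b" = -0.5)),
                        n_cells_per_type = 50, noise_sd = 1, seed = 9)
  fit <- fit_score_effects(sc, variant = "interaction")
  expect_true(all(paste0("age:", fit$groups) %in%
                    names(coef(fit))))
})

test_that("DerSimonian-Laird pooling matches the closed form", {
  m <- meta_random_effects(c(0.01, 0.03), c(0.01, 0.01))
  expect_equal(m$Q, 2, tolerance = 1e-12)
  expect_equal(m$tau2, 1e-4, tolerance = 1e-12)
  expect_equal(m$estimate, 0.02, tolerance = 1e-12)
  expect_equal(m$se, 0.01, tolerance = 1e-12)
  # zero heterogeneity reduces to the fixed-effect estimate
  m0 <- meta_random_effects(c(0.02, 0.02), c(0.01, 0.02))
  expect_equal(m0$Q, 0, tolerance = 1e-12)
  expect_equal(m0$tau2, 0)
  expect_equal(m0$estimate, 0.02, tolerance = 1e-12)
  expect_equal(m0$se, sqrt(1 / 12500), tolerance = 1e-12)
  # singleton input passes through
  m1 <- meta_random_effects(0.5, 0.1)
  expect_equal(m1$estimate, 0.5)
  expect_equal(m1$se, 0.1)
  expect_equal(m1$tau2, 0)
  expect_equal(m1$K, 1)
  expect_error(meta_random_effects(numeric(0), numeric(0)), "at least")
  expect_error(meta_random_effects(c(1, 2), c(0.1, 0)), "positive")
})

test_that("DL pooling agrees with metafor on random instances", {
  library(metafor)
  set.seed(17)
  for (i in 1:40) {
    K <- sample(2:10, 1)
    y <- rnorm(K, 0.02, 0.05)
    se <- runif(K, 0.005, 0.05)
    ours <- meta_random_effects(y, se)
    ref <- rma(yi = y, sei = se, method = "DL")
    expect_equal(ours$estimate, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(ours$se, ref$se, tolerance = 1e-8)
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-8)
  }
})

fake_effects <- function(est, se) {
  structure(list(coefficients = est, se = se, groups = names(est),
                 n_per_group = rep(100L, length(est))),
            class = "gag_effects")
}

test_that("group contrasts pool within labels and z-test between them", {
  eff <- fake_effects(c("T1|a" = 0.5, "T2|b" = 0.0),
                      c("T1|a" = 0.1, "T2|b" = 0.1))
  info <- make_groups(c("T1", "T2"), c("a", "b"), c(1, 1),
                      functional_category = c("A", "B"))
  gc <- group_contrast(eff, info)
  expect_equal(gc$contrasts$z, 3.535534, tolerance = 1e-6)
  expect_equal(gc$contrasts$p, 4.069e-4, tolerance = 1e-3)
  # identical groups give z = 0, p = 1
  eff2 <- fake_effects(c("T1|a" = 0.5, "T2|b" = 0.5),
                       c("T1|a" = 0.1, "T2|b" = 0.1))
  gc2 <- group_contrast(eff2, info)
  expect_equal(gc2$contrasts$z, 0)
  expect_equal(gc2$contrasts$p, 1)
  # unlabeled groups are excluded, with a count
  info3 <- info; info3$functional_category[2] <- NA
  expect_error(gc3 <- group_contrast(eff, info3), NA)
  expect_equal(attr(gc3, "n_unlabeled"), 1)
})

test_that("tissue-cell types with larger planted effects test higher", {
  truth <- list(beta_age = 0.05, beta_sex = 0,
                group_effects = c("T1|a" = 0.8, "T2|b" = 0.7,
                                  "T1|c" = 0.0, "T2|d" = -0.1))
  sc <- simulate_scores(truth, n_cells_per_type = 300, noise_sd = 1,
                        seed = 21)
  fit <- fit_score_effects(sc)
  info <- make_groups(c("T1", "T2", "T1", "T2"), c("a", "b", "c", "d"),
                      rep(0.5, 4),
                      lifespan_label = c("short", "short", "long", "long"))
  gc <- group_contrast(fit, info, grouping = "lifespan_label")
  row <- gc$contrasts[gc$contrasts$label_a == "long", ]
  expect_lt(row$diff, 0)        # long-lived minus short-lived
  expect_lt(row$p, 0.01)
})

test_that("effect comparisons across models use shared groups", {
  eff <- fake_effects(c("T1|a" = 0.5, "T2|b" = 0.1, "T3|c" = -0.4),
                      rep(0.1, 3))
  self <- compare_effects(eff, eff)
  expect_equal(self$r, 1)
  neg <- fake_effects(-eff$coefficients, eff$se)
  expect_equal(compare_effects(eff, neg)$r, -1)
  small <- fake_effects(c("T1|a" = 0.5, "T2|b" = 0.1), rep(0.1, 2))
  expect_error(compare_effects(eff, small), "3 shared")
})

test_that("independent replicates sharing planted group effects correlate", {
  truth <- list(beta_age = 0.05, beta_sex = 0,
                group_effects = c("T1|a" = 0.6, "T1|b" = -0.6,
                                  "T2|c" = 0.3, "T2|d" = -0.3,
                                  "T3|e" = 0))
  f1 <- fit_score_effects(simulate_scores(truth, 200, 1, seed = 31))
  f2 <- fit_score_effects(simulate_scores(truth, 200, 1, seed = 32))
  expect_gt(compare_effects(f1, f2)$r, 0.8)
})
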