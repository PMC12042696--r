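# the synthetic-data generators: reproducibility, planted structure, and the
# statistical features downstream stages rely on

test_that("identical seeds reproduce the proteome bit-identically, distinct seeds differ", {
  cfg <- sim_config(n_proteins = 200, seed = 42)
  g1 <- generate_ev_proteome(cfg)
  g2 <- generate_ev_proteome(cfg)
  expect_identical(g1$matrix$values, g2$matrix$values)
  expect_identical(g1$truth$de_proteins, g2$truth$de_proteins)
  g3 <- generate_ev_proteome(sim_config(n_proteins = 200, seed = 43))
  expect_false(identical(g1$matrix$values, g3$matrix$values))
})

test_that("planted differential set matches the configured fraction", {
  g <- generate_ev_proteome(sim_config(n_proteins = 2000, frac_de = 0.1,
                                       missing_rate = 0, seed = 5))
  expect_length(g$truth$de_proteins, 200)
  g0 <- generate_ev_proteome(sim_config(n_proteins = 500, frac_de = 0,
                                        missing_rate = 0, seed = 5))
  expect_length(g0$truth$de_proteins, 0)
  expect_false(anyNA(g0$matrix$values))
})

test_that("planted group effects are recovered on average across replicates", {
  errs <- vapply(1:20, function(i) {
    g <- generate_ev_proteome(sim_config(n_proteins = 300, frac_de = 0.2,
                                         missing_rate = 0, n_biomarkers = 0,
                                         seed = i))
    x <- g$matrix
    mash <- x$design$group == "MASH"
    lfc <- rowMeans(x$values[, mash]) - rowMeans(x$values[, !mash])
    mean(lfc[names(g$truth$de_proteins)] - g$truth$de_proteins)
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.05)
})

test_that("missingness is left-censoring: censored cells sit at lower intensities", {
  cfg_full <- sim_config(n_proteins = 1000, missing_rate = 0, seed = 9)
  cfg_miss <- sim_config(n_proteins = 1000, missing_rate = 0.2, seed = 9)
  full <- generate_ev_proteome(cfg_full)$matrix$values
  miss <- generate_ev_proteome(cfg_miss)$matrix$values
  censored <- is.na(miss)
  expect_gt(mean(censored), 0.1)
  expect_lt(mean(full[censored]), mean(full[!censored]))
})

test_that("interaction catalog honors weights, uniqueness and the empty case", {
  one_cat <- generate_interaction_catalog(50, 30, category_weights = c(adhesion = 1),
                                          seed = 1)
  expect_true(all(one_cat$category == "adhesion"))
  expect_identical(nrow(generate_interaction_catalog(0, 30, seed = 1)), 0L)

  cat_df <- generate_interaction_catalog(2000, 500, seed = 3, mean_partners = 3)
  expect_false(any(duplicated(cat_df[c("ligand", "receptor", "category")])))
  w <- interaction_categories()
  props <- table(factor(cat_df$category, levels = names(w))) / nrow(cat_df)
  expected <- w / sum(w)
  tol <- 3 * sqrt(expected * (1 - expected) / nrow(cat_df))
  expect_true(all(abs(props - expected) < tol))
})

test_that("cell-type reference plants receptor enrichment only when asked", {
  rs <- sprintf("GENE%05d", 1:50)
  null_ref <- generate_celltype_reference(5, 200, enriched_type = "celltype_02",
                                          receptor_set = rs, boost = 1, seed = 2)
  expect_null(null_ref$truth$enriched_cell_type)
  expect_true(all(null_ref$reference$expression >= 0))

  planted <- generate_celltype_reference(5, 200, enriched_type = "celltype_02",
                                         receptor_set = rs, boost = 5, seed = 2)
  expect_identical(planted$truth$enriched_cell_type, "celltype_02")
  sc <- receptor_enrichment_scores(rs, planted$reference)
  expect_identical(sc$cell_type[sc$rank == 1], "celltype_02")
  expect_error(generate_celltype_reference(5, 200, boost = 0, seed = 2),
               "boost")
})

test_that("fibrosis readout hits the target correlation and its edge cases", {
  g <- generate_ev_proteome(sim_config(n_proteins = 300, missing_rate = 0, seed = 4))
  bio <- g$truth$biomarker_proteins
  m <- colMeans(g$matrix$values[bio, ])

  noiseless <- generate_fibrosis_readout(g$matrix, bio, target_r = 0.5,
                                         seed = 1, noise_sd = 0)
  expect_equal(cor(m, noiseless), 1, tolerance = 1e-12)
  expect_true(all(noiseless > 0))
  expect_error(generate_fibrosis_readout(g$matrix, bio, target_r = 1), "target_r")

  rbar <- vapply(1:30, function(i) {
    g_i <- generate_ev_proteome(sim_config(n_proteins = 300, missing_rate = 0,
                                           seed = 100 + i))
    b_i <- g_i$truth$biomarker_proteins
    rd <- generate_fibrosis_readout(g_i$matrix, b_i, target_r = 0.7,
                                    seed = 200 + i)
    mean(apply(g_i$matrix$values[b_i, ], 1, cor, y = rd))
  }, numeric(1))
  expect_lt(abs(mean(rbar) - 0.7), 0.1)
})

test_that("stage trajectories are monotone exactly for the planted genes", {
  prof <- generate_stage_trajectories(monotone_genes = c("GENE00003", "GENE00007"),
                                      n_genes = 50, seed = 6)
  ord <- seq_along(prof$stages)
  rho <- apply(prof$means, 1, cor, y = ord, method = "spearman")
  expect_true(all(rho[c("GENE00003", "GENE00007")] == 1))
  expect_error(generate_stage_trajectories(stages = c("a", "b"), seed = 1),
               "3 ordered stages")
  expect_error(generate_stage_trajectories(stages = c("a", "b", "b"), seed = 1),
               "duplicate")
})

test_that("mixtures are exact convex combinations and validate the simplex", {
  ref <- generate_celltype_reference(4, 100, seed = 8)$reference
  onehot <- generate_mixture(ref, c(0, 0, 1, 0), noise_sd = 0, seed = 1)
  expect_equal(unname(onehot$profile), unname(ref$expression[3, ]),
               tolerance = 1e-12)
  expect_error(generate_mixture(ref, c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
  noisy <- generate_mixture(ref, rep(0.25, 4), noise_sd = 5, seed = 2)
  expect_true(all(noisy$profile >= 0))
  expect_equal(sum(noisy$truth$true_proportions), 1)
})
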