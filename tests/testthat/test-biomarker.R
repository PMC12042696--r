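# fibrosis-biomarker triage: correlation filter, stage-trend filter,
# variability ranking and the composed chain

test_that("Pearson correlation matches the covariance formula and cor.test", {
  expect_equal(pearson_correlation(1:5, 2 * (1:5))$r, 1)
  expect_equal(pearson_correlation(1:5, -(1:5) + 7)$r, -1)
  x <- c(1, 2, 4, 5); y <- c(1, 3, 3, 6)
  got <- pearson_correlation(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_oracle)
  ct <- cor.test(x, y)
  expect_equal(got$r, unname(ct$estimate))
  expect_equal(got$p, ct$p.value)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("correlation is symmetric and invariant to positive affine maps", {
  set.seed(51)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(pearson_correlation(x, y)$r, pearson_correlation(y, x)$r)
  expect_equal(pearson_correlation(3 * x + 2, y)$r, pearson_correlation(x, y)$r)
  expect_equal(pearson_correlation(x, 0.5 * y - 4)$p, pearson_correlation(x, y)$p)
})

test_that("correlation filter retains positive significant associations only", {
  g <- generate_ev_proteome(sim_config(n_proteins = 300, missing_rate = 0, seed = 53))
  bio <- g$truth$biomarker_proteins
  rd <- generate_fibrosis_readout(g$matrix, bio, target_r = 0.7, seed = 54)
  f1 <- correlation_filter(g$matrix, rd)
  expect_true(all(f1$r[f1$retained] > 0))
  expect_true(all(f1$p[f1$retained] < 0.05))
  expect_true(all(bio %in% f1$protein_id[f1$retained]))

  none <- correlation_filter(g$matrix, rd, alpha = .Machine$double.xmin)
  expect_identical(sum(none$retained), 0L)
  bad <- setNames(rd, rev(paste0("zz", seq_along(rd))))
  expect_error(correlation_filter(g$matrix, bad), "do not match")
})

test_that("null readout retains about the positive half of the nominal rate", {
  retained <- vapply(1:30, function(i) {
    g <- generate_ev_proteome(sim_config(n_proteins = 400, missing_rate = 0,
                                         frac_de = 0, n_biomarkers = 0,
                                         seed = 300 + i))
    rd <- generate_fibrosis_readout(g$matrix, rownames(g$matrix$values)[1:2],
                                    target_r = 0, seed = 400 + i)
    mean(correlation_filter(g$matrix, rd)$retained)
  }, numeric(1))
  expect_lt(abs(mean(retained) - 0.025), 0.01)
})

test_that("stage-trend filter retains exactly the monotone genes", {
  prof <- generate_stage_trajectories(monotone_genes = c("GENE00001", "GENE00010"),
                                      n_genes = 40, seed = 55)
  res <- stage_trend_filter(prof, rownames(prof$means))
  expect_true(all(c("GENE00001", "GENE00010") %in% res$gene[res$retained]))
  dec_prof <- prof
  dec_prof$means["GENE00002", ] <- rev(sort(dec_prof$means["GENE00002", ]))
  res2 <- stage_trend_filter(dec_prof, "GENE00002")
  expect_equal(res2$rho, -1)
  expect_false(res2$retained)
  expect_error(stage_trend_filter(prof, "NOTAGENE"), "absent")
})

test_that("variability ranking pools within-group CVs on the linear scale", {
  # two groups of two samples; hand-computed linear-scale CVs
  dsn <- data.frame(sample_id = c("h1", "h2", "m1", "m2"),
                    group = c("h", "h", "m", "m"), medium = "WEGG",
                    donor_id = c("d1", "d2", "d3", "d4"),
                    stringsAsFactors = FALSE)
  v <- matrix(log2(c(10, 10, 20, 20,        # constant within groups: CV 0
                     8, 12, 16, 24,         # same CV in both groups
                     5, 15, 10, 30)),       # larger CV
              3, 4, byrow = TRUE,
              dimnames = list(c("PA", "PB", "PC"), dsn$sample_id))
  x <- ev_matrix(v, rep(3L, 3), dsn)
  rk <- variability_ranking(x, c("PC", "PA", "PB"))
  expect_identical(rk$protein_id, c("PA", "PB", "PC"))
  expect_equal(rk$pooled_cv[1], 0)
  cv_b <- sd(c(8, 12)) / 10                  # equals sd(c(16,24))/20
  expect_equal(rk$pooled_cv[2], cv_b)
  expect_identical(rk$rank, 1:3)
})

test_that("cross-modality concordance requires donor pairing", {
  ev <- setNames(c(1, 2, 3, 4), paste0("d", 1:4))
  expect_equal(cross_modality_concordance(ev, ev)$r, 1)
  mr <- setNames(c(2, 4, 7, 8), paste0("d", c(2, 1, 3, 4)))
  got <- cross_modality_concordance(ev, mr)
  expect_equal(got$r, cor(c(1, 2, 3, 4), c(4, 2, 7, 8)))
  expect_error(cross_modality_concordance(ev, setNames(1:4, paste0("x", 1:4))),
               "paired")
})

test_that("the triage chain is monotone and drops non-monotone distractors", {
  g <- generate_ev_proteome(sim_config(n_proteins = 500, missing_rate = 0,
                                       frac_de = 0, seed = 57))
  bio <- g$truth$biomarker_proteins
  rd <- generate_fibrosis_readout(g$matrix, bio, target_r = 0.8, seed = 58)
  # distractor: correlated with the readout but non-monotone across stages
  distractor <- setdiff(rownames(g$matrix$values), bio)[1]
  g$matrix$values[distractor, ] <- mean(g$matrix$values[distractor, ]) +
    0.9 * scale(rd)[, 1] + rnorm(length(rd), 0, 0.3)
  prof <- generate_stage_trajectories(monotone_genes = bio,
                                      gene_symbols = rownames(g$matrix$values),
                                      seed = 59)
  tri <- triage(g$matrix, rd, prof)
  f1_ids <- tri$correlation$protein_id[tri$correlation$retained]
  f2_ids <- tri$trend$gene[tri$trend$retained]
  expect_true(distractor %in% f1_ids)
  expect_false(distractor %in% tri$final)
  expect_true(all(tri$final %in% f2_ids))
  expect_true(all(f2_ids %in% f1_ids))
  expect_true(all(bio %in% tri$final))

  empty <- triage(g$matrix, rd, prof, alpha = .Machine$double.xmin)
  expect_identical(empty$final, character(0))
  expect_match(empty$notes[1], "skipped")
})
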