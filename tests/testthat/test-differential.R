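# per-protein OLS, count-aware variance moderation, moderated test, BH and
# hypergeometric over-representation

test_that("per-protein OLS reproduces hand-computed effects and variances", {
  v <- matrix(c(2, 2, 2, 5, 5, 5,          # constant groups: effect 3, s2 0
                1, 2, 3, 4, 5, 6), 2, 6, byrow = TRUE)
  x <- two_group_matrix(v)
  fit <- fit_linear_models(x, ~ group)
  expect_equal(fit$effect, c(3, 3))
  expect_equal(fit$s2, c(0, 1))            # (1+0+1)+(1+0+1) over d = 4
  expect_identical(fit$df, c(4L, 4L))
  expect_equal(attr(fit, "contrast_variance_factor"), 1 / 3 + 1 / 3)
})

test_that("rank-deficient designs are rejected naming the aliased columns", {
  v <- matrix(rnorm(12), 2, 6)
  x <- two_group_matrix(v)
  x$design$dup <- x$design$group           # aliased with group
  expect_error(fit_linear_models(x, ~ group + dup), "aliased")
})

test_that("moderation shrinks variances within containment bounds and flat data is a fixed point", {
  set.seed(21)
  n <- 400
  counts <- sample(1:30, n, replace = TRUE)
  s2 <- (0.5 / counts) * 4 / rchisq(n, 4)
  mod <- moderate_variances(s2, 4, counts)
  s0 <- mod$s2_prior
  expect_true(all(mod$s2_post >= pmin(s2, s0) - 1e-12))
  expect_true(all(mod$s2_post <= pmax(s2, s0) + 1e-12))

  # constant variances, flat trend: prior and posterior equal the constant
  expect_warning(flat <- moderate_variances(rep(2, 50), 4, rep(7, 50)),
                 "no positive root")
  expect_equal(unname(flat$s2_prior), rep(2, 50))
  expect_equal(unname(flat$s2_post), rep(2, 50))

  forced <- moderate_variances(rep(2, 50), 4, rep(7, 50), d0_override = 3)
  expect_equal(unname(forced$s2_post), rep(2, 50))   # (3*2 + 4*2)/7
  expect_error(moderate_variances(rep(0, 10), 4, rep(5, 10)), "zero")
})

test_that("forced prior df reproduces the classical limits exactly", {
  v <- matrix(rnorm(6 * 30, sd = 0.4), 30, 6) +
    matrix(rep(c(0, 0.5), each = 3), 30, 6, byrow = TRUE)
  x <- two_group_matrix(v)
  res0 <- ev_differential(x, d0_override = 0)
  t_classic <- apply(v, 1, function(r) t.test(r[4:6], r[1:3], var.equal = TRUE)$statistic)
  expect_equal(unname(res0$t), unname(t_classic), tolerance = 1e-12)
  p_classic <- apply(v, 1, function(r) t.test(r[4:6], r[1:3], var.equal = TRUE)$p.value)
  expect_equal(unname(res0$p), unname(p_classic), tolerance = 1e-12)

  # d0 = Inf with a flat trend on constant variances: pooled-variance z
  vv <- matrix(c(1, 2, 3, 5, 6, 7), 40, 6, byrow = TRUE)
  xx <- two_group_matrix(vv)
  resi <- ev_differential(xx, d0_override = Inf, n_bins = 1)
  z_expected <- 4 / sqrt((1 / 3 + 1 / 3) * 1)     # effect 4, pooled s2 = 1
  expect_equal(unname(resi$t), rep(z_expected, 40), tolerance = 1e-12)
  expect_equal(unname(resi$p), rep(2 * pnorm(-z_expected), 40), tolerance = 1e-12)
})

test_that("moderated test matches direct arithmetic and is sign-symmetric", {
  tt <- moderated_test(3, 1, df = 2, d0 = 2, v = 2 / 3)
  expect_equal(tt$t, 3 / sqrt(2 / 3))
  expect_equal(tt$p, 2 * pt(-3 / sqrt(2 / 3), df = 4))
  expect_identical(moderated_test(0, 1, 4, 2, 1)$p, 1)
  expect_identical(moderated_test(0, 1, 4, 2, 1)$t, 0)
  expect_equal(moderated_test(-1.7, 0.8, 4, 3, 0.5)$p,
               moderated_test(1.7, 0.8, 4, 3, 0.5)$p)
  expect_error(moderated_test(1, 1, 4, 2, v = 0), "v must be")
})

test_that("prior df recovery from a known scaled inverse-chi-square prior", {
  set.seed(31)
  n <- 5000; d0_true <- 6; d <- 4
  sigma2 <- 0.1 * d0_true / rchisq(n, d0_true)
  s2 <- sigma2 * rchisq(n, d) / d
  mod <- moderate_variances(s2, d, counts = rep(10, n))
  expect_lt(abs(mod$d0 - d0_true) / d0_true, 0.2)
})

test_that("moderation agrees with an independent empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(32)
  n <- 4000; d0_true <- 5; d <- 4
  sigma2 <- 0.08 * d0_true / rchisq(n, d0_true)
  s2 <- sigma2 * rchisq(n, d) / d
  mod <- moderate_variances(s2, d, counts = rep(10, n))
  sq <- limma::squeezeVar(s2, df = d)
  expect_lt(abs(mod$d0 - sq$df.prior) / sq$df.prior, 0.25)
  expect_gt(cor(mod$s2_post, sq$var.post), 0.99)
})

test_that("BH step-up equals the brute-force min-over-suffix oracle", {
  expect_identical(bh_fdr(0.031), 0.031)
  p4 <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p4), bh_bruteforce(p4))
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(41)
  for (i in 1:50) {
    p <- runif(sample(1:80, 1))
    expect_equal(bh_fdr(p), bh_bruteforce(p))
  }
})

test_that("hypergeometric ORA matches exact enumeration on a small universe", {
  universe <- sprintf("G%02d", 1:20)
  hits <- universe[1:5]
  gs <- list(s4 = universe[2:5], s10 = universe[6:15], s1 = universe[20])
  res <- ora_enrichment(hits, universe, gs)
  for (nm in names(gs)) {
    k <- length(intersect(hits, gs[[nm]]))
    K <- length(gs[[nm]])
    expect_equal(res$p[res$set == nm], hyper_tail_enum(k, K, 20, 5))
  }
  # exhaustive draw: hit set = universe -> overlap = set size, p = 1
  res_all <- ora_enrichment(universe, universe, gs)
  expect_equal(res_all$overlap, res_all$set_size)
  expect_true(all(res_all$p == 1))
  # zero overlap is never evidence of enrichment
  res0 <- ora_enrichment(universe[1:5], universe, list(s = universe[6:9]))
  expect_equal(res0$p, 1)
  expect_error(ora_enrichment("A", character(0), gs), "universe")
  expect_error(ora_enrichment("ZZZ", universe, gs), "subset")
})

test_that("discoveries increase with planted effect size at matched data", {
  n_disc <- vapply(c(1, 2.5, 4), function(es) {
    g <- generate_ev_proteome(sim_config(n_proteins = 1500, frac_de = 0.15,
                                         effect_size_sd = es, missing_rate = 0,
                                         n_biomarkers = 0, seed = 77))
    res <- ev_differential(g$matrix, within = c(medium = "WEGG"))
    sum(res$significant)
  }, numeric(1))
  expect_true(all(diff(n_disc) >= 0))
  expect_gt(n_disc[3], n_disc[1])
})

test_that("donor blocking is accepted for paired contrasts", {
  g <- generate_ev_proteome(sim_config(n_proteins = 120, missing_rate = 0, seed = 15))
  res <- ev_differential(g$matrix, contrast_factor = "medium",
                         within = c(group = "MASH"), block = "donor_id")
  expect_identical(nrow(res), 120L)
  expect_true(all(is.finite(res$t)))
})
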