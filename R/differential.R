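#' Per-protein ordinary least squares on a shared design
#'
#' Fits the same linear model to every protein of a complete-case intensity
#' matrix and extracts one coefficient (the tested contrast) together with
#' the residual variance and residual degrees of freedom. The design must be
#' full rank and leave positive residual df.
#'
#' @param x An [ev_matrix()] without missing values.
#' @param formula Model formula over design columns (e.g. `~ group`).
#' @param coef Name of the coefficient to extract; defaults to the last
#'   column of the design matrix.
#' @return Data frame with per-protein `protein_id`, `effect` (log2 units),
#'   `s2` (residual variance), `df` (residual df, shared) and attribute
#'   `contrast_variance_factor` (the unscaled variance of the coefficient,
#'   e.g. 1/n1 + 1/n2 for a two-group contrast).
#' @export
fit_linear_models <- function(x, formula = ~ group, coef = NULL) {
  stopifnot(inherits(x, "ev_matrix"))
  if (anyNA(x$values))
    stop("matrix contains missing values; run complete_case_filter() first")
  dsn <- x$design
  X <- stats::model.matrix(formula, data = dsn)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  n <- nrow(X)
  d <- n - qrX$rank
  if (d <= 0) stop("no residual degrees of freedom (n = rank of design)")
  if (is.null(coef)) coef <- colnames(X)[ncol(X)]
  if (!coef %in% colnames(X))
    stop("coefficient '", coef, "' not in design columns: ",
         paste(colnames(X), collapse = ", "))
  tv <- t(x$values)                      # samples x proteins
  B <- qr.coef(qrX, tv)                  # coefs x proteins
  R <- qr.resid(qrX, tv)
  s2 <- colSums(R^2) / d
  xtx_inv <- chol2inv(qr.R(qrX))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  out <- data.frame(protein_id = rownames(x$values),
                    effect = B[coef, ], s2 = s2, df = d,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "contrast_variance_factor") <- xtx_inv[coef, coef]
  attr(out, "coef") <- coef
  out
}

# invert the trigamma function (trigamma is strictly decreasing on (0, Inf))
inv_trigamma <- function(x) {
  if (x <= trigamma(1e7)) return(Inf)
  if (x >= trigamma(1e-6)) return(1e-6)
  stats::uniroot(function(ly) trigamma(exp(ly)) - x,
                 interval = log(c(1e-6, 1e7)), tol = 1e-12)$root |> exp()
}

#' Empirical-Bayes variance moderation with a peptide-count trend
#'
#' Implements count-aware variance shrinkage for low-replicate proteomics:
#'
#' 1. The count-to-variance trend is fitted by binning proteins into
#'    equal-occupancy bins of log(peptide count), taking the bin median of
#'    log residual variance, and interpolating linearly between bin centres
#'    (flat extrapolation outside). This is the prior variance s0^2(c).
#' 2. The prior degrees of freedom d0 are estimated by moment matching: if
#'    s2/s0^2 follows an F(d, d0) distribution, the variance of
#'    log(s2/s0^2) is trigamma(d/2) + trigamma(d0/2); d0 is recovered by
#'    inverting the trigamma function. When the equation has no positive
#'    root, d0 = Inf (complete shrinkage to the trend) with a warning.
#' 3. Because the bin median of log s2 estimates log s0^2 plus the log
#'    median of the F(d, d0) distribution (which is below zero at small d),
#'    the raw trend is divided by qf(0.5, d, d0) once d0 is known; without
#'    this the posterior variances would be systematically biased whenever
#'    the median of F(d, d0) is far from 1. The correction is part of the
#'    estimation procedure: a forced `d0_override` takes the binned trend
#'    as-is.
#' 4. Posterior variance: s2_post = (d0 s0^2(c) + d s2) / (d0 + d);
#'    s2_post = s0^2(c) when d0 = Inf; s2_post = s2 when d0 = 0.
#'
#' @param s2 Per-protein residual variances (>= 0).
#' @param df Residual degrees of freedom (scalar).
#' @param counts Per-protein peptide counts (>= 1).
#' @param n_bins Number of equal-occupancy trend bins (>= 10 recommended);
#'   falls back to a single global bin, with a warning, when there are
#'   fewer proteins than bins.
#' @param d0_override Optional forced prior df (0 disables shrinkage, `Inf`
#'   shrinks fully to the trend).
#' @return Object of class `moderation_fit`: list with `d0`, `s2_prior`
#'   (per protein), `s2_post`, `trend` (bin centres and median log s2) and
#'   `s2_prior_fn` (function of peptide count).
#' @export
moderate_variances <- function(s2, df, counts, n_bins = 10, d0_override = NULL) {
  if (length(counts) != length(s2)) stop("counts and s2 lengths differ")
  if (any(s2 < 0, na.rm = TRUE)) stop("residual variances must be >= 0")
  if (any(counts < 1)) stop("peptide counts must be >= 1")
  if (all(s2 == 0)) stop("all residual variances are zero (degenerate data)")
  df <- df[1]
  n <- length(s2)
  pos <- which(is.finite(s2) & s2 > 0)
  lc <- log(counts)

  if (length(pos) < n_bins) {
    warning("fewer usable proteins than bins; using a single global bin")
    n_bins <- 1L
  }
  bin <- ceiling(rank(lc[pos], ties.method = "first") * n_bins / length(pos))
  centers <- tapply(lc[pos], bin, mean)
  med_log_s2 <- tapply(log(s2[pos]), bin, stats::median)
  # collapse duplicate centres (few distinct counts) so interpolation is valid
  ord <- order(centers)
  centers <- as.numeric(centers[ord]); med_log_s2 <- as.numeric(med_log_s2[ord])
  keep <- !duplicated(round(centers, 12))
  if (sum(keep) < length(centers)) {
    med_log_s2 <- tapply(med_log_s2, cumsum(keep), mean)
    centers <- centers[keep]
  }
  trend_fn_raw <- if (length(centers) == 1L) {
    function(lcx) rep(med_log_s2[1], length(lcx))
  } else {
    function(lcx) stats::approx(centers, med_log_s2, xout = lcx, rule = 2)$y
  }
  log_s0_raw <- trend_fn_raw(lc)

  estimated <- is.null(d0_override)
  if (!estimated) {
    d0 <- d0_override
    if (d0 < 0) stop("d0_override must be >= 0")
  } else {
    z <- log(s2[pos]) - log_s0_raw[pos]
    rhs <- stats::var(z) - trigamma(df / 2)
    if (!is.finite(rhs) || rhs <= 0) {
      warning("trigamma moment equation has no positive root; prior df set to Inf")
      d0 <- Inf
    } else {
      d0 <- 2 * inv_trigamma(rhs)
    }
  }

  # median-consistency correction of the trend (see step 3 above); part of
  # the estimation procedure only -- a forced d0 takes the trend as-is
  log_corr <- if (estimated && is.finite(d0) && d0 > 0)
    log(stats::qf(0.5, df, d0)) else 0
  log_s0 <- log_s0_raw - log_corr
  s2_prior <- exp(log_s0)
  s2_post <- if (!is.finite(d0)) s2_prior
  else if (d0 == 0) s2
  else (d0 * s2_prior + df * s2) / (d0 + df)

  structure(list(d0 = d0, df = df, s2_prior = s2_prior, s2_post = s2_post,
                 trend = data.frame(center_log_count = centers,
                                    median_log_s2 = med_log_s2),
                 log_correction = log_corr,
                 s2_prior_fn = function(c) exp(trend_fn_raw(log(c)) - log_corr)),
            class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf("moderation_fit: prior df d0 = %s, residual df d = %g, %d trend bins\n",
              format(x$d0, digits = 4), x$df, nrow(x$trend)))
  invisible(x)
}

#' Moderated t-statistic and two-sided p-value
#'
#' t = effect / sqrt(v * s2_post), referred to a t distribution with
#' d + d0 degrees of freedom; the normal limit is used when d0 = Inf.
#'
#' @param effect Contrast estimates (log2 units).
#' @param s2_post Posterior variances (> 0).
#' @param df Residual df.
#' @param d0 Prior df.
#' @param v Contrast variance factor (> 0), e.g. 1/n1 + 1/n2.
#' @return Data frame with `t` and `p`.
#' @export
moderated_test <- function(effect, s2_post, df, d0, v) {
  if (any(v <= 0)) stop("contrast variance factor v must be > 0")
  if (any(s2_post <= 0)) stop("posterior variances must be > 0")
  t_stat <- effect / sqrt(v * s2_post)
  p <- if (is.finite(d0)) 2 * stats::pt(-abs(t_stat), df = df + d0)
  else 2 * stats::pnorm(-abs(t_stat))
  data.frame(t = t_stat, p = p)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Hypergeometric over-representation of a hit set in gene sets
#'
#' For each set, p is the upper tail of the hypergeometric law for drawing
#' at least k members of a K-sized set (restricted to the universe) in
#' |hits| draws without replacement from the universe; BH adjustment across
#' sets.
#'
#' @param hit_set Symbols of interest (subset of `universe`).
#' @param universe Background symbols (non-empty).
#' @param gene_sets Named list of symbol sets.
#' @return Data frame per set: `set`, `overlap`, `set_size` (in universe),
#'   `hits`, `universe`, `p`, `q`, ordered by `p`.
#' @export
ora_enrichment <- function(hit_set, universe, gene_sets) {
  universe <- unique(normalize_symbols(universe))
  if (!length(universe)) stop("empty universe")
  hit_set <- unique(normalize_symbols(hit_set))
  stray <- setdiff(hit_set, universe)
  if (length(stray))
    stop("hit_set must be a subset of the universe; outside: ",
         paste(utils::head(stray, 5), collapse = ", "))
  N <- length(universe); nh <- length(hit_set)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(normalize_symbols(gene_sets[[nm]])), universe)
    K <- length(members)
    k <- length(intersect(hit_set, members))
    p <- stats::phyper(k - 1, K, N - K, nh, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, hits = nh, universe = N,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}

#' Moderated differential abundance between two groups
#'
#' One-stop wrapper reproducing the stratified group comparisons of an EV
#' proteomics study: optionally restrict to a stratum (e.g. one culture
#' medium), fit per-protein OLS on `~ group`, moderate variances with the
#' peptide-count trend, compute moderated t and BH q-values, and flag
#' significance at the configured FDR.
#'
#' @param x A complete-case [ev_matrix()].
#' @param contrast_factor Design column to test (default `"group"`).
#' @param test_level,ref_level Levels compared (`test_level - ref_level`);
#'   defaults: the last and first observed level.
#' @param within Optional named character vector restricting samples, e.g.
#'   `c(medium = "WEGG")`.
#' @param block Optional design column added as a blocking factor (e.g.
#'   `"donor_id"` for paired designs). Default none.
#' @param n_bins,d0_override Passed to [moderate_variances()].
#' @param fdr_threshold Significance threshold on q (default 0.05).
#' @return Data frame of class `ev_differential` with per-protein `effect`
#'   (log2 fold-change), `s2`, `df`, `s2_post`, `t`, `p`, `q`,
#'   `peptide_count`, `significant`; attributes `d0`, `contrast`,
#'   `fdr_threshold`, `moderation`.
#' @export
ev_differential <- function(x, contrast_factor = "group",
                            test_level = NULL, ref_level = NULL,
                            within = NULL, block = NULL,
                            n_bins = 10, d0_override = NULL,
                            fdr_threshold = 0.05) {
  stopifnot(inherits(x, "ev_matrix"))
  if (!is.null(within)) {
    keep <- rep(TRUE, nrow(x$design))
    for (nm in names(within)) keep <- keep & x$design[[nm]] == within[[nm]]
    x <- ev_subset(x, samples = which(keep))
  }
  dsn <- x$design
  dsn[[contrast_factor]] <- as.character(dsn[[contrast_factor]])
  lv <- unique(dsn[[contrast_factor]])
  ref_level <- ref_level %||% lv[1]
  test_level <- test_level %||% setdiff(lv, ref_level)[1]
  if (min(table(dsn[[contrast_factor]])) < 2)
    stop("need at least 2 samples per compared level of '", contrast_factor, "'")
  dsn[[contrast_factor]] <- factor(dsn[[contrast_factor]],
                                   levels = c(ref_level, test_level))
  x$design <- dsn
  fml <- if (is.null(block)) stats::as.formula(paste("~", contrast_factor))
  else stats::as.formula(paste("~", block, "+", contrast_factor))
  fit <- fit_linear_models(x, fml,
                           coef = paste0(contrast_factor, test_level))
  v <- attr(fit, "contrast_variance_factor")
  mod <- moderate_variances(fit$s2, fit$df, x$peptide_counts,
                            n_bins = n_bins, d0_override = d0_override)
  tst <- moderated_test(fit$effect, mod$s2_post, fit$df, mod$d0, v)
  out <- data.frame(protein_id = fit$protein_id, effect = fit$effect,
                    s2 = fit$s2, df = fit$df, s2_post = mod$s2_post,
                    t = tst$t, p = tst$p, q = bh_fdr(tst$p),
                    peptide_count = unname(x$peptide_counts),
                    stringsAsFactors = FALSE)
  out$significant <- out$q < fdr_threshold
  attr(out, "d0") <- mod$d0
  attr(out, "contrast") <- sprintf("%s: %s vs %s", contrast_factor,
                                   test_level, ref_level)
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "contrast_variance_factor") <- v
  attr(out, "moderation") <- mod
  class(out) <- c("ev_differential", "data.frame")
  out
}

#' @export
print.ev_differential <- function(x, ...) {
  cat(sprintf("ev_differential (%s): %d proteins, %d significant at q < %g (d0 = %s)\n",
              attr(x, "contrast"), nrow(x), sum(x$significant),
              attr(x, "fdr_threshold"), format(attr(x, "d0"), digits = 4)))
  invisible(x)
}
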