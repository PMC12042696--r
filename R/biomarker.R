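#' Pearson correlation with a two-sided t-based p-value
#'
#' r is the sample Pearson correlation; p comes from the transform
#' t = r sqrt((n - 2) / (1 - r^2)) with n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 3, non-zero variance).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

# vectorised per-row Pearson r and p against one response
row_correlations <- function(values, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(y)
  if (method == "spearman") {
    values <- t(apply(values, 1, rank))
    y <- rank(y)
  }
  r <- as.numeric(stats::cor(t(values), y))
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p[abs(r) >= 1] <- 0
  data.frame(r = r, p = p)
}

#' Filter proteins by positive correlation with a fibrosis readout
#'
#' Per protein, the correlation of its log2 intensity across samples with
#' the per-sample readout (e.g. secreted pro-collagen 1a1). Retains
#' proteins with p below `alpha` and r > 0 (positive association with
#' fibrogenesis). No multiplicity correction by default, matching the raw
#' p < 0.05 screening convention; a BH option is provided.
#'
#' @param x A complete-case [ev_matrix()].
#' @param readout Named numeric vector aligned with the matrix samples.
#' @param alpha Retention threshold on p (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param adjust If `TRUE`, apply BH and threshold q instead of p.
#' @return Data frame per protein: `protein_id`, `r`, `p` (and `q` if
#'   adjusted), `retained`.
#' @export
correlation_filter <- function(x, readout, alpha = 0.05,
                               method = c("pearson", "spearman"),
                               adjust = FALSE) {
  stopifnot(inherits(x, "ev_matrix"))
  method <- match.arg(method)
  if (is.null(names(readout)) ||
      !setequal(names(readout), colnames(x$values)))
    stop("readout sample ids do not match the intensity matrix samples")
  readout <- readout[colnames(x$values)]
  if (anyNA(x$values)) stop("matrix contains missing values; filter first")
  stats_df <- row_correlations(x$values, readout, method)
  out <- data.frame(protein_id = rownames(x$values), stats_df,
                    stringsAsFactors = FALSE)
  if (adjust) {
    out$q <- bh_fdr(out$p)
    out$retained <- out$q < alpha & out$r > 0
  } else {
    out$retained <- out$p < alpha & out$r > 0
  }
  rownames(out) <- NULL
  out
}

#' Filter genes by a monotone increase across ordered disease stages
#'
#' Computes, per candidate gene, the Spearman rank correlation of its stage
#' means with the stage order, and retains genes at or above the threshold
#' (default 1: strictly monotone increase, the strict reading of a
#' "continuous increase" across stages).
#'
#' @param profile A `stage_profile` (see [generate_stage_trajectories()]):
#'   list with `means` (genes x stages) and `stages`.
#' @param candidates Gene symbols (subset of the profile's genes).
#' @param threshold Minimum Spearman rho for retention, in \[-1, 1\].
#' @return Data frame per candidate: `gene`, `rho`, `retained`.
#' @export
stage_trend_filter <- function(profile, candidates, threshold = 1) {
  stopifnot(inherits(profile, "stage_profile") ||
              (is.list(profile) && !is.null(profile$means)))
  means <- profile$means
  if (ncol(means) < 3) stop("need at least 3 ordered stages")
  candidates <- normalize_symbols(candidates)
  missing_g <- setdiff(candidates, rownames(means))
  if (length(missing_g))
    stop("candidates absent from the stage profile: ",
         paste(utils::head(missing_g, 10), collapse = ", "))
  ord <- seq_len(ncol(means))
  rho <- vapply(candidates, function(g)
    stats::cor(means[g, ], ord, method = "spearman"), numeric(1))
  data.frame(gene = candidates, rho = unname(rho),
             retained = unname(rho) >= threshold - 1e-12,
             stringsAsFactors = FALSE)
}

#' Rank candidate biomarkers by within-group variability
#'
#' Computes, per candidate, the coefficient of variation on the linear
#' intensity scale (2^log2) within each sample group, pools groups by the
#' root-mean-square of group CVs, and ranks ascending (lowest variability
#' first). Groups with fewer than 2 samples are excluded from pooling with
#' a warning.
#'
#' @param x An [ev_matrix()].
#' @param candidates Protein ids present in the matrix.
#' @param group_col Design column defining the groups (default `"group"`).
#' @return Data frame ordered by rank: `protein_id`, `pooled_cv`, `rank`.
#' @export
variability_ranking <- function(x, candidates, group_col = "group") {
  stopifnot(inherits(x, "ev_matrix"))
  candidates <- normalize_symbols(candidates)
  missing_p <- setdiff(candidates, rownames(x$values))
  if (length(missing_p))
    stop("candidates absent from matrix: ", paste(missing_p, collapse = ", "))
  groups <- split(seq_len(ncol(x$values)), x$design[[group_col]])
  small <- names(groups)[lengths(groups) < 2]
  if (length(small)) {
    warning("groups with < 2 samples excluded from pooling: ",
            paste(small, collapse = ", "))
    groups <- groups[lengths(groups) >= 2]
  }
  if (!length(groups)) stop("no group with >= 2 samples")
  lin <- 2^x$values[candidates, , drop = FALSE]
  cv2 <- vapply(groups, function(cols) {
    m <- lin[, cols, drop = FALSE]
    (apply(m, 1, stats::sd) / rowMeans(m))^2
  }, numeric(length(candidates)))
  cv2 <- matrix(cv2, nrow = length(candidates))
  pooled <- sqrt(rowMeans(cv2))
  out <- data.frame(protein_id = candidates, pooled_cv = pooled,
                    stringsAsFactors = FALSE)
  out <- out[order(out$pooled_cv, out$protein_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Concordance of per-donor EV protein levels with hepatic mRNA
#'
#' @param ev_levels,tissue_mrna Named numeric vectors paired by donor id.
#' @return List with `r`, `p`, `n` (Pearson, as in
#'   [pearson_correlation()]).
#' @export
cross_modality_concordance <- function(ev_levels, tissue_mrna) {
  if (is.null(names(ev_levels)) || is.null(names(tissue_mrna)) ||
      !setequal(names(ev_levels), names(tissue_mrna)))
    stop("ev_levels and tissue_mrna must be paired by donor id")
  tissue_mrna <- tissue_mrna[names(ev_levels)]
  pearson_correlation(ev_levels, tissue_mrna)
}

#' Three-filter biomarker triage
#'
#' Screens EV proteins for fibrosis-biomarker candidates: (1) positive
#' correlation with the fibrosis readout at `alpha`; (2) monotone increase
#' of the gene's expression across ordered disease stages (candidates
#' absent from the stage profile fail this filter); (3) ranking of the
#' survivors by pooled within-group variability, lowest first. The report
#' carries every intermediate statistic.
#'
#' @param x A complete-case [ev_matrix()].
#' @param readout Named per-sample readout vector.
#' @param profile A `stage_profile`.
#' @param alpha Filter-1 threshold on raw p.
#' @param trend_threshold Filter-2 Spearman threshold (default 1, strict
#'   monotonicity).
#' @param method Correlation method for filter 1.
#' @return Object of class `biomarker_report`: list with `correlation`
#'   (filter-1 table), `trend` (filter-2 table), `ranking` (filter-3
#'   table), `final` (ordered surviving protein ids) and `notes`.
#' @export
triage <- function(x, readout, profile, alpha = 0.05, trend_threshold = 1,
                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  notes <- character(0)
  f1 <- correlation_filter(x, readout, alpha = alpha, method = method)
  survivors1 <- f1$protein_id[f1$retained]
  if (!length(survivors1)) {
    notes <- c(notes, "no protein passed the correlation filter; stages 2-3 skipped")
    return(structure(list(correlation = f1, trend = NULL, ranking = NULL,
                          final = character(0), notes = notes),
                     class = "biomarker_report"))
  }
  in_profile <- intersect(survivors1, rownames(profile$means))
  absent <- setdiff(survivors1, in_profile)
  if (length(absent))
    notes <- c(notes, sprintf("%d filter-1 survivors absent from the stage profile fail filter 2",
                              length(absent)))
  if (!length(in_profile)) {
    notes <- c(notes, "no filter-1 survivor present in the stage profile")
    return(structure(list(correlation = f1, trend = NULL, ranking = NULL,
                          final = character(0), notes = notes),
                     class = "biomarker_report"))
  }
  f2 <- stage_trend_filter(profile, in_profile, threshold = trend_threshold)
  survivors2 <- f2$gene[f2$retained]
  if (!length(survivors2)) {
    notes <- c(notes, "no protein passed the stage-trend filter")
    return(structure(list(correlation = f1, trend = f2, ranking = NULL,
                          final = character(0), notes = notes),
                     class = "biomarker_report"))
  }
  f3 <- variability_ranking(x, survivors2)
  structure(list(correlation = f1, trend = f2, ranking = f3,
                 final = f3$protein_id, notes = notes),
            class = "biomarker_report")
}

#' @export
print.biomarker_report <- function(x, ...) {
  n1 <- if (!is.null(x$correlation)) sum(x$correlation$retained) else 0
  n2 <- if (!is.null(x$trend)) sum(x$trend$retained) else 0
  cat(sprintf("biomarker_report: %d correlated, %d monotone, final list: %s\n",
              n1, n2,
              if (length(x$final)) paste(x$final, collapse = ", ") else "(empty)"))
  for (nt in x$notes) cat("  note: ", nt, "\n", sep = "")
  invisible(x)
}
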