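#' Collective receptor enrichment score per cell type
#'
#' Operationalises the "collective expression" of a receptor set in each
#' cell type of an expression reference: every gene's expression is first
#' normalised to its fraction across cell types (gene-wise sum 1; all-zero
#' genes dropped), and the score E_c of cell type c is the mean fraction
#' over the receptors found in the reference. Fractions make scores
#' comparable across receptor sets and insensitive to a few highly
#' expressed genes; an unnormalised mean-expression variant is available
#' for sensitivity analysis.
#'
#' @param receptors Receptor gene symbols (at least one must be present in
#'   the reference).
#' @param reference A [celltype_reference()].
#' @param normalize `"fraction"` (default) or `"mean"` (unnormalised mean
#'   expression).
#' @return Data frame of class `enrichment_scores`: `cell_type`, `score`,
#'   `rank` (1 = highest score); attributes `n_receptors_used` and
#'   `dropped_receptors`.
#' @export
receptor_enrichment_scores <- function(receptors, reference,
                                       normalize = c("fraction", "mean")) {
  stopifnot(inherits(reference, "celltype_reference"))
  normalize <- match.arg(normalize)
  receptors <- unique(normalize_symbols(receptors))
  expr <- reference$expression
  nonzero <- colSums(expr) > 0
  usable_genes <- colnames(expr)[nonzero]
  used <- intersect(receptors, usable_genes)
  dropped <- setdiff(receptors, used)
  if (!length(used))
    stop("no receptor present in the reference; missing: ",
         paste(utils::head(receptors, 10), collapse = ", "))
  mat <- expr[, used, drop = FALSE]
  if (normalize == "fraction")
    mat <- sweep(mat, 2, colSums(mat), "/")
  score <- rowMeans(mat)
  out <- data.frame(cell_type = reference$cell_types, score = unname(score),
                    stringsAsFactors = FALSE)
  out$rank <- as.integer(rank(-out$score, ties.method = "min"))
  class(out) <- c("enrichment_scores", "data.frame")
  attr(out, "n_receptors_used") <- length(used)
  attr(out, "dropped_receptors") <- dropped
  attr(out, "normalize") <- normalize
  out
}

#' Permutation null for receptor enrichment scores
#'
#' Scores `n_perm` random gene sets of the same size (drawn without
#' replacement from the reference's non-zero genes) and reports, per cell
#' type, the z-score of the observed score against the null and the
#' empirical p with the add-one correction
#' p = (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param receptors Receptor gene symbols.
#' @param reference A [celltype_reference()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed (fixed seed gives identical z and p).
#' @param normalize Passed to [receptor_enrichment_scores()].
#' @return The [receptor_enrichment_scores()] data frame with extra columns
#'   `z` and `p_empirical`.
#' @export
permutation_null <- function(receptors, reference, n_perm = 1000, seed = 1L,
                             normalize = c("fraction", "mean")) {
  stopifnot(inherits(reference, "celltype_reference"))
  normalize <- match.arg(normalize)
  if (n_perm < 100) stop("n_perm must be >= 100")
  obs <- receptor_enrichment_scores(receptors, reference, normalize)
  n_used <- attr(obs, "n_receptors_used")
  expr <- reference$expression
  usable <- colnames(expr)[colSums(expr) > 0]
  if (n_used > length(usable))
    stop("receptor set larger than the usable gene universe")
  frac <- if (normalize == "fraction")
    sweep(expr[, usable, drop = FALSE], 2,
          colSums(expr[, usable, drop = FALSE]), "/")
  else expr[, usable, drop = FALSE]
  set.seed(substream_seed(seed, "permutation_null"))
  null_scores <- vapply(seq_len(n_perm), function(i) {
    rowMeans(frac[, sample(length(usable), n_used), drop = FALSE])
  }, numeric(nrow(expr)))                       # cell types x n_perm
  mu <- rowMeans(null_scores)
  sdv <- apply(null_scores, 1, stats::sd)
  obs$z <- (obs$score - mu) / sdv
  obs$p_empirical <- (1 + rowSums(null_scores >= obs$score)) / (n_perm + 1)
  obs
}

#' Receptor abundance screen across tissues
#'
#' Identical contract to [receptor_enrichment_scores()] with tissues as the
#' row dimension of the reference.
#'
#' @inheritParams receptor_enrichment_scores
#' @param tissue_reference A [celltype_reference()] whose rows are tissues.
#' @return An `enrichment_scores` data frame (column `cell_type` holds the
#'   tissue labels).
#' @export
tissue_screen <- function(receptors, tissue_reference,
                          normalize = c("fraction", "mean")) {
  receptor_enrichment_scores(receptors, tissue_reference, normalize)
}

#' Pseudo-bulk a cells x genes count matrix into a cell-type reference
#'
#' Cells are first normalised to a common library size (the mean total
#' count, unless given), then averaged per labelled type. Types with zero
#' cells are dropped with a warning.
#'
#' @param cell_matrix Non-negative cells x genes matrix (gene columns
#'   named).
#' @param cell_labels Per-cell type labels (length = rows of
#'   `cell_matrix`).
#' @param target_libsize Common library size; default mean of cell totals.
#' @return A [celltype_reference()].
#' @export
pseudobulk_from_cells <- function(cell_matrix, cell_labels,
                                  target_libsize = NULL) {
  if (!is.matrix(cell_matrix) || any(cell_matrix < 0))
    stop("cell_matrix must be a non-negative matrix")
  if (length(cell_labels) != nrow(cell_matrix))
    stop("every cell must carry a label")
  totals <- rowSums(cell_matrix)
  if (any(totals == 0)) stop("cells with zero total counts are not allowed")
  target_libsize <- target_libsize %||% mean(totals)
  norm <- cell_matrix * (target_libsize / totals)
  labs <- if (is.factor(cell_labels)) levels(cell_labels)
  else unique(as.character(cell_labels))
  empty <- setdiff(labs, as.character(cell_labels))
  if (length(empty)) {
    warning("cell types with zero cells dropped: ",
            paste(empty, collapse = ", "))
    labs <- setdiff(labs, empty)
  }
  profiles <- t(vapply(labs, function(lb) {
    colMeans(norm[cell_labels == lb, , drop = FALSE])
  }, numeric(ncol(cell_matrix))))
  rownames(profiles) <- labs
  colnames(profiles) <- normalize_symbols(colnames(cell_matrix))
  celltype_reference(profiles)
}
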