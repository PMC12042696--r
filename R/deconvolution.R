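#' Build a marker-gene signature matrix from a cell-type reference
#'
#' For each cell type, markers are the genes with the highest ratio of that
#' type's expression to the maximum across all other types (genes expressed
#' in one type only rank first with an infinite ratio); ties are broken by
#' absolute expression, then symbol order. The union of per-type markers
#' forms the signature rows.
#'
#' @param reference A [celltype_reference()] with at least two cell types.
#' @param n_markers_per_type Markers selected per type (>= 1); capped at the
#'   gene count with a warning.
#' @return Object of class `signature_matrix`: list with `matrix` (genes x
#'   cell types) and `markers_by_type`.
#' @export
build_signature_matrix <- function(reference, n_markers_per_type = 50L) {
  stopifnot(inherits(reference, "celltype_reference"))
  if (n_markers_per_type < 1) stop("n_markers_per_type must be >= 1")
  expr <- reference$expression
  K <- nrow(expr)
  if (K < 2) stop("reference has a single cell type; nothing to deconvolve")
  G <- ncol(expr)
  if (n_markers_per_type > G) {
    warning("n_markers_per_type exceeds the gene count; using all genes")
    n_markers_per_type <- G
  }
  markers_by_type <- lapply(seq_len(K), function(k) {
    others_max <- apply(expr[-k, , drop = FALSE], 2, max)
    ratio <- ifelse(others_max == 0,
                    ifelse(expr[k, ] > 0, Inf, 0),
                    expr[k, ] / others_max)
    ord <- order(-ratio, -expr[k, ], colnames(expr))
    colnames(expr)[ord[seq_len(n_markers_per_type)]]
  })
  names(markers_by_type) <- rownames(expr)
  markers <- sort(unique(unlist(markers_by_type)))
  sig <- t(expr)[markers, , drop = FALSE]
  structure(list(matrix = sig, markers_by_type = markers_by_type),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature_matrix: %d marker genes x %d cell types\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Non-negative least-squares deconvolution of an EV profile
#'
#' Estimates the cell-type composition of a bulk EV profile by solving
#' min ||S w - y||^2 subject to w >= 0 over the genes shared between the
#' profile and the signature, then normalising w to the simplex. Profile
#' and signature are each rescaled by a single global factor before the
#' solve (so the proportions reflect relative contribution, not library
#' size, and exact mixtures are recovered exactly).
#'
#' @param ev_profile Named non-negative gene vector (protein intensities on
#'   the linear scale; symbols shared with the signature genes).
#' @param signature A [build_signature_matrix()] result, or a genes x cell
#'   types non-negative matrix.
#' @return Object of class `deconvolution_result`: list with `proportions`
#'   (simplex vector over cell types), `residual` (norm on the fitted
#'   scale), `n_genes_used`, `dropped_genes`.
#' @export
nnls_deconvolve <- function(ev_profile, signature) {
  S <- if (inherits(signature, "signature_matrix")) signature$matrix else signature
  if (is.null(names(ev_profile))) stop("ev_profile must be a named gene vector")
  names(ev_profile) <- normalize_symbols(names(ev_profile))
  shared <- intersect(names(ev_profile), rownames(S))
  if (length(shared) < 2)
    stop("profile and signature share fewer than 2 genes")
  y <- ev_profile[shared]
  if (all(y == 0)) stop("all-zero profile over the shared genes")
  A <- S[shared, , drop = FALSE]
  # single global scale factors: conditioning only, proportions unaffected
  y_sc <- y / sum(y)
  A_sc <- A / mean(colSums(A))
  fit <- pracma::lsqnonneg(A_sc, y_sc)
  w <- fit$x
  if (sum(w) <= 0)
    stop("degenerate fit: all mixture weights zero")
  pi_hat <- w / sum(w)
  names(pi_hat) <- colnames(S)
  structure(list(proportions = pi_hat,
                 residual = sqrt(sum((A_sc %*% w - y_sc)^2)),
                 n_genes_used = length(shared),
                 dropped_genes = setdiff(names(ev_profile), shared)),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("deconvolution_result over %d genes (residual %.3g):\n",
              x$n_genes_used, x$residual))
  print(round(x$proportions, 4))
  invisible(x)
}
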