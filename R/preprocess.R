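#' Keep only proteins quantified in every sample
#'
#' Label-free EV proteomes contain intensity-dependent missing values; the
#' pipeline's differential stage requires complete cases, so proteins with
#' any missing entry are removed (no imputation).
#'
#' @param x An [ev_matrix()].
#' @param quiet Suppress the before/after report.
#' @return The filtered `ev_matrix`. Idempotent.
#' @export
complete_case_filter <- function(x, quiet = FALSE) {
  stopifnot(inherits(x, "ev_matrix"))
  keep <- rowSums(is.na(x$values)) == 0
  if (!any(keep))
    stop("complete-case filter removed every protein; inspect the missingness ",
         "pattern (overall missing fraction ",
         sprintf("%.2f", mean(is.na(x$values))), ")")
  if (!quiet)
    message(sprintf("complete-case filter: %d of %d proteins retained",
                    sum(keep), nrow(x$values)))
  ev_subset(x, proteins = which(keep))
}

#' Overlap of a protein set with reference EV catalogs
#'
#' Venn-style QC against curated EV protein catalogs: for each catalog, the
#' intersection size with the query set and the fraction of the query it
#' covers. Symbol matching is case-insensitive and duplicate catalog entries
#' are ignored.
#'
#' @param proteins Character vector of query symbols (non-empty).
#' @param catalogs Named list of catalog symbol sets (e.g. from
#'   [read_gmt()]).
#' @return Data frame with one row per catalog: `catalog`, `n_query`,
#'   `n_catalog`, `n_overlap`, `fraction` (of the query), `n_query_only`.
#' @export
catalog_overlap <- function(proteins, catalogs) {
  proteins <- unique(normalize_symbols(proteins))
  if (!length(proteins)) stop("empty query protein set")
  stopifnot(is.list(catalogs), !is.null(names(catalogs)))
  rows <- lapply(names(catalogs), function(nm) {
    members <- unique(normalize_symbols(catalogs[[nm]]))
    ov <- length(intersect(proteins, members))
    data.frame(catalog = nm, n_query = length(proteins),
               n_catalog = length(members), n_overlap = ov,
               fraction = ov / length(proteins),
               n_query_only = length(proteins) - ov,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarise MISEV positive/negative EV marker panels per sample
#'
#' For every marker category (positive: transmembrane/GPI-anchored,
#' cytosolic; negative: lipoprotein and organelle contaminants) and sample:
#' the mean log2 intensity over the detected members and the number detected
#' out of the set size. Also returns a heatmap-ready marker x sample matrix.
#'
#' @param x An [ev_matrix()].
#' @param positive_sets,negative_sets Named lists of marker symbol sets
#'   (non-empty).
#' @return List with `summary` (long data frame: `category`, `class`,
#'   `sample`, `mean_log2`, `n_detected`, `set_size`) and `marker_matrix`
#'   (detected markers x samples, `NA` where undetected).
#' @export
misev_marker_panel <- function(x, positive_sets, negative_sets) {
  stopifnot(inherits(x, "ev_matrix"))
  if (!length(positive_sets) || !length(negative_sets) ||
      any(!lengths(positive_sets)) || any(!lengths(negative_sets)))
    stop("marker sets must be non-empty")
  all_sets <- c(lapply(positive_sets, normalize_symbols),
                lapply(negative_sets, normalize_symbols))
  cls <- rep(c("positive", "negative"),
             c(length(positive_sets), length(negative_sets)))
  samples <- colnames(x$values)
  rows <- list()
  for (i in seq_along(all_sets)) {
    members <- all_sets[[i]]
    present <- intersect(members, rownames(x$values))
    if (!length(present))
      warning("no marker of category '", names(all_sets)[i],
              "' detected in any sample; category reported as absent")
    for (s in samples) {
      vals <- if (length(present)) x$values[present, s] else numeric(0)
      det <- vals[!is.na(vals)]
      rows[[length(rows) + 1L]] <- data.frame(
        category = names(all_sets)[i], class = cls[i], sample = s,
        mean_log2 = if (length(det)) mean(det) else NA_real_,
        n_detected = length(det), set_size = length(members),
        stringsAsFactors = FALSE)
    }
  }
  detected_markers <- intersect(unique(unlist(all_sets)), rownames(x$values))
  marker_matrix <- if (length(detected_markers))
    x$values[detected_markers, , drop = FALSE]
  else matrix(numeric(0), 0, length(samples), dimnames = list(NULL, samples))
  list(summary = do.call(rbind, rows), marker_matrix = marker_matrix)
}
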