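#' Construct an EV intensity matrix
#'
#' Container for a proteins x samples table of log2 intensities together with
#' the per-protein peptide (or spectra) counts used by the variance-moderation
#' stage and the sample design (group, culture medium, donor).
#'
#' @param values Numeric matrix, proteins in rows (rownames are protein/gene
#'   symbols), samples in columns (colnames are sample ids). Values are log2
#'   intensities; `NA` marks a protein not detected in a sample.
#' @param peptide_counts Positive integer vector, one entry per protein.
#' @param design Data frame with columns `sample_id`, `group`, `medium`,
#'   `donor_id`; one row per sample, in column order of `values`.
#' @return An object of class `ev_matrix`.
#' @export
ev_matrix <- function(values, peptide_counts, design) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("protein ids (rownames) must be present and unique; duplicates: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("sample ids (colnames) must be present and unique")
  if (length(peptide_counts) != nrow(values))
    stop("peptide_counts length (", length(peptide_counts),
         ") must equal the number of proteins (", nrow(values), ")")
  if (any(!is.finite(peptide_counts)) || any(peptide_counts < 1))
    stop("peptide_counts must be finite and >= 1")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  needed <- c("sample_id", "group", "medium", "donor_id")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols))
    stop("design lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!identical(as.character(design$sample_id), colnames(values)))
    stop("design sample_id must match matrix columns in order")
  structure(
    list(values = values,
         peptide_counts = stats::setNames(as.numeric(peptide_counts), rownames(values)),
         design = design),
    class = "ev_matrix")
}

#' @export
dim.ev_matrix <- function(x) dim(x$values)

#' @export
print.ev_matrix <- function(x, ...) {
  cat(sprintf("ev_matrix: %d proteins x %d samples\n", nrow(x$values), ncol(x$values)))
  cat(sprintf("  groups: %s | media: %s\n",
              paste(unique(x$design$group), collapse = "/"),
              paste(unique(x$design$medium), collapse = "/")))
  miss <- mean(is.na(x$values))
  cat(sprintf("  missing fraction: %.3f\n", miss))
  invisible(x)
}

#' Subset an ev_matrix by proteins and/or samples
#'
#' @param x An [ev_matrix()].
#' @param proteins Character or logical/integer index over proteins.
#' @param samples Character or logical/integer index over samples.
#' @return The subsetted `ev_matrix`.
#' @export
ev_subset <- function(x, proteins = NULL, samples = NULL) {
  stopifnot(inherits(x, "ev_matrix"))
  v <- x$values
  pc <- x$peptide_counts
  dsn <- x$design
  if (!is.null(proteins)) {
    v <- v[proteins, , drop = FALSE]
    pc <- pc[rownames(v)]
  }
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    dsn <- dsn[match(colnames(v), dsn$sample_id), , drop = FALSE]
    rownames(dsn) <- NULL
  }
  ev_matrix(v, pc, dsn)
}

#' Read a protein intensity table and its sample design
#'
#' The intensity table is tab-delimited with a header: a protein-id column,
#' a peptide-count column and one column per sample. The design table has
#' columns `sample_id`, `group`, `medium`, `donor_id`.
#'
#' A raw value of 0 under `raw_scale` is treated as not-detected (missing),
#' never as -Inf: label-free zeros are censoring, not abundance.
#'
#' @param path Path to the intensity TSV.
#' @param design_path Path to the design TSV.
#' @param raw_scale If `TRUE`, values are raw intensities and are log2
#'   transformed on load (zeros become `NA`). If `FALSE` (default) the file
#'   already holds log2 values.
#' @param id_col,count_col Column names of the protein id and peptide count.
#' @param quiet Suppress the load report message.
#' @return An [ev_matrix()].
#' @export
load_intensity_table <- function(path, design_path, raw_scale = FALSE,
                                 id_col = "protein_id",
                                 count_col = "peptide_count",
                                 quiet = FALSE) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c(id_col, count_col) %in% names(tab)))
    stop("intensity table must contain columns '", id_col, "' and '", count_col, "'")
  ids <- normalize_symbols(tab[[id_col]])
  if (anyDuplicated(ids))
    stop("duplicate protein ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dsn <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  sample_cols <- setdiff(names(tab), c(id_col, count_col))
  orphans_tab <- setdiff(sample_cols, dsn$sample_id)
  orphans_dsn <- setdiff(dsn$sample_id, sample_cols)
  if (length(orphans_tab) || length(orphans_dsn))
    stop("sample/design mismatch; columns without design rows: [",
         paste(orphans_tab, collapse = ", "), "]; design rows without columns: [",
         paste(orphans_dsn, collapse = ", "), "]")
  v <- as.matrix(tab[, dsn$sample_id, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- ids
  if (raw_scale) {
    v[!is.na(v) & v <= 0] <- NA_real_
    v <- log2(v)
  }
  out <- ev_matrix(v, tab[[count_col]], dsn)
  if (!quiet)
    message(sprintf("loaded %d proteins x %d samples (missing fraction %.3f)",
                    nrow(v), ncol(v), mean(is.na(v))))
  out
}

#' Write an intensity matrix and design to TSV
#'
#' Round-trips bit-exactly with [load_intensity_table()] (with
#' `raw_scale = FALSE`) and preserves label order.
#'
#' @param x An [ev_matrix()].
#' @param path,design_path Output paths.
#' @return Invisibly, `x`.
#' @export
write_intensity_table <- function(x, path, design_path) {
  stopifnot(inherits(x, "ev_matrix"))
  vals <- matrix(sprintf("%.17g", x$values), nrow(x$values),
                 dimnames = dimnames(x$values))   # full precision round-trip
  vals[is.na(x$values)] <- NA
  tab <- data.frame(protein_id = rownames(x$values),
                    peptide_count = unname(x$peptide_counts),
                    vals, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$design, design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' @param path Path to a GMT file (set name, description, tab-separated
#'   members).
#' @return Named list of character vectors, symbols upper-cased.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, normalize_symbols)
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Per-sample median centering
#'
#' Optional normalisation switch (off by default throughout the pipeline):
#' subtracts each sample's median log2 intensity.
#'
#' @param x An [ev_matrix()].
#' @return The centred `ev_matrix`.
#' @export
median_center <- function(x) {
  stopifnot(inherits(x, "ev_matrix"))
  med <- apply(x$values, 2, stats::median, na.rm = TRUE)
  x$values <- sweep(x$values, 2, med, "-")
  x
}
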