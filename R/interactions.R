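#' Read a ligand-receptor interaction catalog
#'
#' Four-column TSV with header (`ligand`, `receptor`, `category`, `source`);
#' extra columns are preserved but ignored. Symbols are upper-cased and
#' duplicate (ligand, receptor, category) triples dropped.
#'
#' @param path Path to the catalog TSV.
#' @return Data frame of interaction records.
#' @export
read_interaction_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("ligand", "receptor", "category")
  if (!all(needed %in% names(tab)))
    stop("catalog must contain columns: ", paste(needed, collapse = ", "))
  tab$ligand <- normalize_symbols(tab$ligand)
  tab$receptor <- normalize_symbols(tab$receptor)
  tab <- tab[!duplicated(tab[needed]), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Map selected EV proteins, as ligands, to cognate receptors
#'
#' Intersects a selection of differentially abundant EV proteins with the
#' ligand column of a curated interaction catalog; every matching record
#' becomes one binding-partner row annotated with the ligand's effect and
#' FDR. Rows are ordered by category, then ligand, then receptor, so output
#' is byte-stable.
#'
#' @param diff_result An [ev_differential()] result (or data frame with
#'   `protein_id`, `effect`, `q`).
#' @param catalog Interaction catalog data frame
#'   ([read_interaction_catalog()] or [generate_interaction_catalog()]).
#' @param selection Which proteins act as ligands:
#'   `"upregulated_significant"` (default; q below threshold and positive
#'   effect), `"all_significant"`, or `"all"`.
#' @param q_threshold FDR threshold for the significance-based selections.
#' @return Data frame of class `binding_partner_table` with columns
#'   `ligand`, `receptor`, `category`, `ligand_effect`, `ligand_q`;
#'   attribute `summary` holds per-category counts and the total.
#' @export
map_ligands_to_receptors <- function(diff_result, catalog,
                                     selection = c("upregulated_significant",
                                                   "all_significant", "all"),
                                     q_threshold = 0.05) {
  selection <- match.arg(selection)
  stopifnot(all(c("protein_id", "effect", "q") %in% names(diff_result)))
  sel <- switch(selection,
                upregulated_significant =
                  diff_result$q < q_threshold & diff_result$effect > 0,
                all_significant = diff_result$q < q_threshold,
                all = rep(TRUE, nrow(diff_result)))
  chosen <- diff_result[sel, , drop = FALSE]
  chosen$protein_id <- normalize_symbols(chosen$protein_id)
  if (!nrow(chosen))
    warning("selection '", selection, "' yields no proteins; empty table")
  idx <- match(normalize_symbols(catalog$ligand), chosen$protein_id)
  hit <- !is.na(idx)
  tab <- data.frame(ligand = normalize_symbols(catalog$ligand[hit]),
                    receptor = normalize_symbols(catalog$receptor[hit]),
                    category = catalog$category[hit],
                    ligand_effect = chosen$effect[idx[hit]],
                    ligand_q = chosen$q[idx[hit]],
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$category, tab$ligand, tab$receptor), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("binding_partner_table", "data.frame")
  attr(tab, "selection") <- selection
  attr(tab, "summary") <- partition_counts(tab)
  tab
}

#' Per-category counts of a binding-partner table
#'
#' Counts interactions over the closed category label set (zero for absent
#' categories); the total always equals the row count.
#'
#' @param table A binding-partner table (or any data frame with a
#'   `category` column).
#' @param categories Closed label set; defaults to the names of
#'   [interaction_categories()]. Unknown labels in the table are an error.
#' @return Named list with `counts` (named integer vector) and `total`.
#' @export
partition_counts <- function(table, categories = names(interaction_categories())) {
  stopifnot("category" %in% names(table))
  unknown <- setdiff(unique(table$category), categories)
  if (length(unknown))
    stop("unknown interaction categories: ", paste(unknown, collapse = ", "))
  counts <- vapply(categories, function(cc) sum(table$category == cc), integer(1))
  list(counts = counts, total = nrow(table))
}

#' Significantly changed ligands per interaction category
#'
#' @param table A [map_ligands_to_receptors()] result.
#' @param q_threshold Highlight rows with `ligand_q` below this value.
#' @return The highlighted subset, ordered by category then decreasing
#'   absolute ligand effect.
#' @export
highlight_significant_ligands <- function(table, q_threshold = 0.05) {
  stopifnot(all(c("ligand_q", "ligand_effect", "category") %in% names(table)))
  out <- table[table$ligand_q < q_threshold, , drop = FALSE]
  out <- out[order(out$category, -abs(out$ligand_effect), out$ligand, out$receptor),
             , drop = FALSE]
  rownames(out) <- NULL
  out
}
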