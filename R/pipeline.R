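#' Validate a pipeline run configuration
#'
#' Reads a YAML configuration (or accepts a list), checks every constraint,
#' and reports all violations at once. Unknown keys produce a warning only
#' (forward compatibility).
#'
#' Recognised keys: `seed` (non-negative integer), `output_dir`, `stages`
#' (subset of simulate, preprocess, differential, ora, interactions,
#' celltargets, deconvolution, biomarker), `simulate` (arguments for
#' [sim_config()]), `thresholds` (`fdr`, `alpha` in (0,1); `trend` in
#' \[-1,1\]; `n_perm` >= 100; `n_markers_per_type` >= 1), `inputs` (file
#' paths used when `simulate` is not among the stages), `selection`
#' (ligand selection rule).
#'
#' @param config Path to a YAML file, or a configuration list.
#' @return A validated list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  known <- c("seed", "output_dir", "stages", "simulate", "thresholds",
             "inputs", "selection")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    warning("unknown config keys ignored: ", paste(unknown, collapse = ", "))
  errors <- character(0)
  add_err <- function(msg) errors <<- c(errors, msg)

  seed <- config$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed) || seed < 0)
    add_err("seed must be a non-negative integer")
  all_stages <- c("simulate", "preprocess", "differential", "ora",
                  "interactions", "celltargets", "deconvolution", "biomarker")
  stages <- config$stages %||% all_stages
  bad_stages <- setdiff(stages, all_stages)
  if (length(bad_stages))
    add_err(paste0("unknown stages: ", paste(bad_stages, collapse = ", ")))

  th <- config$thresholds %||% list()
  fdr <- th$fdr %||% 0.05
  alpha <- th$alpha %||% 0.05
  trend <- th$trend %||% 1
  n_perm <- th$n_perm %||% 200L
  n_markers <- th$n_markers_per_type %||% 50L
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1) add_err("fdr must lie in (0,1)")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    add_err("alpha must lie in (0,1)")
  if (!is.numeric(trend) || trend < -1 || trend > 1)
    add_err("trend must lie in [-1,1]")
  if (!is.numeric(n_perm) || n_perm < 100) add_err("n_perm must be >= 100")
  if (!is.numeric(n_markers) || n_markers < 1)
    add_err("n_markers_per_type must be >= 1")

  if (!"simulate" %in% stages) {
    needed <- c("intensity", "design")
    paths <- unlist(config$inputs[needed])
    if (any(!needed %in% names(config$inputs %||% list())))
      add_err("without the simulate stage, inputs$intensity and inputs$design are required")
    for (p in paths) if (!file.exists(p))
      add_err(paste0("input path does not exist: ", p))
  }
  selection <- config$selection %||% "upregulated_significant"
  if (!selection %in% c("upregulated_significant", "all_significant", "all"))
    add_err("selection must be one of upregulated_significant/all_significant/all")

  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  structure(list(seed = as.integer(seed),
                 output_dir = config$output_dir %||% "evcargo_run",
                 stages = stages,
                 simulate = config$simulate %||% list(),
                 thresholds = list(fdr = fdr, alpha = alpha, trend = trend,
                                   n_perm = as.integer(n_perm),
                                   n_markers_per_type = as.integer(n_markers)),
                 inputs = config$inputs %||% list(),
                 selection = selection),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = 10)
  path
}

#' Run the full EV-cargo analysis pipeline
#'
#' Executes the requested stages in dependency order (simulate/load ->
#' preprocess -> differential -> \{ora, interactions -> celltargets,
#' deconvolution\} -> biomarker), writing each stage's outputs (TSV, GMT,
#' JSON) to the output directory before the next stage starts, and a
#' consolidated JSON run report at the end. With a fixed seed, repeated
#' runs are byte-identical.
#'
#' @param config A [validate_config()] result, a config list, or a YAML
#'   path.
#' @param output_dir Overrides the config's output directory.
#' @param include_timing If `TRUE` the report records wall-clock seconds
#'   (off by default so outputs are reproducible byte-for-byte).
#' @return Invisibly, the run report list.
#' @export
run_pipeline <- function(config, output_dir = NULL, include_timing = FALSE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out_dir <- output_dir %||% config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  th <- config$thresholds
  seed <- config$seed
  t_start <- Sys.time()

  deps <- list(preprocess = "simulate", differential = "preprocess",
               ora = "differential", interactions = "differential",
               celltargets = "interactions", deconvolution = "preprocess",
               biomarker = "preprocess")
  for (st in setdiff(stages, "simulate")) {
    need <- deps[[st]]
    ok <- need %in% stages ||
      (need == "simulate" && all(c("intensity", "design") %in% names(config$inputs)))
    if (!ok)
      stop("stage '", st, "' requires stage '", need,
           "' (not requested and no file inputs provided)")
  }

  report <- list(package_version = as.character(utils::packageVersion("evcargo")),
                 seed = seed, thresholds = th, stages = list())
  warn_log <- character(0)
  run_stage <- function(name, fun) {
    res <- withCallingHandlers(fun(), warning = function(w) {
      warn_log <<- c(warn_log, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    res
  }
  state <- new.env(parent = emptyenv())

  if ("simulate" %in% stages) {
    report$stages$simulate <- run_stage("simulate", function() {
      sim_args <- config$simulate
      sim_args$seed <- seed
      cf <- do.call(sim_config, sim_args)
      gen <- generate_ev_proteome(cf)
      state$config_sim <- cf
      state$raw <- gen$matrix
      state$truth <- gen$truth
      write_intensity_table(gen$matrix, file.path(out_dir, "intensity.tsv"),
                            file.path(out_dir, "design.tsv"))
      universe <- rownames(gen$matrix$values)
      state$catalogs <- generate_catalog_sets(universe, seed = seed)
      write_gmt(state$catalogs, file.path(out_dir, "ev_catalogs.gmt"))
      state$panels <- generate_marker_panels(universe, seed = seed)
      write_gmt(c(state$panels$positive, state$panels$negative),
                file.path(out_dir, "misev_panels.gmt"))
      state$pathways <- generate_pathway_sets(universe, seed = seed)
      write_gmt(state$pathways, file.path(out_dir, "pathways.gmt"))
      state$catalog <- generate_interaction_catalog(
        n_ligands = 300, n_receptors = 200, seed = seed,
        universe = universe, universe_overlap = 0.6)
      write_tsv(state$catalog, file.path(out_dir, "interaction_catalog.tsv"))
      receptor_universe <- unique(state$catalog$receptor)
      ref_genes <- c(receptor_universe,
                     sprintf("GENE%05d", seq_len(800)))
      gen_ref <- generate_celltype_reference(
        n_celltypes = 10, n_genes = length(ref_genes),
        enriched_type = "celltype_03",
        receptor_set = receptor_universe, boost = 5, seed = seed,
        gene_symbols = ref_genes)
      state$reference <- gen_ref$reference
      state$truth$enriched_cell_type <- gen_ref$truth$enriched_cell_type
      write_tsv(data.frame(cell_type = state$reference$cell_types,
                           state$reference$expression, check.names = FALSE),
                file.path(out_dir, "celltype_reference.tsv"))
      bio <- state$truth$biomarker_proteins
      complete_rows <- rowSums(is.na(gen$matrix$values)) == 0
      if (length(bio) && all(complete_rows[bio])) {
        state$readout <- generate_fibrosis_readout(gen$matrix, bio,
                                                   target_r = 0.7, seed = seed)
        write_tsv(data.frame(sample_id = names(state$readout),
                             procollagen_1a1 = unname(state$readout)),
                  file.path(out_dir, "fibrosis_readout.tsv"))
      }
      state$profile <- generate_stage_trajectories(
        monotone_genes = bio, seed = seed,
        gene_symbols = universe)
      write_tsv(data.frame(gene = rownames(state$profile$means),
                           state$profile$means, check.names = FALSE),
                file.path(out_dir, "stage_profile.tsv"))
      prop <- c(0.55, 0.15, 0.1, 0.08, 0.05, 0.03, 0.02, 0.01, 0.005, 0.005)
      mix <- generate_mixture(state$reference, prop, noise_sd = 0.05, seed = seed)
      state$mixture <- mix
      write_tsv(data.frame(gene = names(mix$profile),
                           intensity = unname(mix$profile)),
                file.path(out_dir, "ev_mixture_profile.tsv"))
      write_json_out(list(de_proteins = as.list(state$truth$de_proteins),
                          biomarker_proteins = state$truth$biomarker_proteins,
                          enriched_cell_type = state$truth$enriched_cell_type,
                          true_proportions = as.list(mix$truth$true_proportions),
                          seed_used = seed),
                     file.path(out_dir, "truth.json"))
      list(n_proteins = nrow(gen$matrix$values),
           n_samples = ncol(gen$matrix$values),
           n_planted_de = length(state$truth$de_proteins),
           biomarkers = state$truth$biomarker_proteins)
    })
  }

  if ("preprocess" %in% stages) {
    report$stages$preprocess <- run_stage("preprocess", function() {
      if (is.null(state$raw)) {
        state$raw <- load_intensity_table(config$inputs$intensity,
                                          config$inputs$design,
                                          raw_scale = isTRUE(config$inputs$raw_scale),
                                          quiet = TRUE)
        if (!is.null(config$inputs$catalogs))
          state$catalogs <- read_gmt(config$inputs$catalogs)
        if (!is.null(config$inputs$interaction_catalog))
          state$catalog <- read_interaction_catalog(config$inputs$interaction_catalog)
      }
      state$filtered <- complete_case_filter(state$raw, quiet = TRUE)
      ov <- NULL
      if (!is.null(state$catalogs)) {
        ov <- catalog_overlap(rownames(state$filtered$values), state$catalogs)
        write_tsv(ov, file.path(out_dir, "catalog_overlap.tsv"))
      }
      if (!is.null(state$panels)) {
        pan <- misev_marker_panel(state$filtered, state$panels$positive,
                                  state$panels$negative)
        write_tsv(pan$summary, file.path(out_dir, "misev_summary.tsv"))
      }
      write_intensity_table(state$filtered,
                            file.path(out_dir, "intensity_complete.tsv"),
                            file.path(out_dir, "design_complete.tsv"))
      c(list(n_before = nrow(state$raw$values),
             n_complete = nrow(state$filtered$values)),
        if (!is.null(ov))
          stats::setNames(as.list(round(100 * ov$fraction, 1)),
                          paste0("pct_in_", ov$catalog)))
    })
  }

  if ("differential" %in% stages) {
    report$stages$differential <- run_stage("differential", function() {
      x <- state$filtered
      media <- unique(x$design$medium)
      groups <- unique(x$design$group)
      res <- list()
      for (m in media) {
        key <- paste0("group_within_", m)
        res[[key]] <- ev_differential(x, contrast_factor = "group",
                                      within = c(medium = m),
                                      fdr_threshold = th$fdr)
      }
      for (g in groups) {
        key <- paste0("medium_within_", g)
        res[[key]] <- ev_differential(x, contrast_factor = "medium",
                                      within = c(group = g),
                                      fdr_threshold = th$fdr)
      }
      for (key in names(res))
        write_tsv(as.data.frame(res[[key]]),
                  file.path(out_dir, paste0("differential_", key, ".tsv")))
      state$differential <- res
      lapply(res, function(r) list(n_significant = sum(r$significant),
                                   d0 = unname(attr(r, "d0"))))
    })
  }

  if ("ora" %in% stages) {
    report$stages$ora <- run_stage("ora", function() {
      main <- state$differential[[1]]
      universe <- main$protein_id
      sets <- state$pathways %||% state$catalogs
      if (is.null(sets)) return(list(skipped = "no gene sets available"))
      up <- main$protein_id[main$significant & main$effect > 0]
      down <- main$protein_id[main$significant & main$effect < 0]
      out <- list()
      for (dir_nm in c("up", "down")) {
        hits <- if (dir_nm == "up") up else down
        if (!length(hits)) next
        tab <- ora_enrichment(hits, universe, sets)
        write_tsv(tab, file.path(out_dir, paste0("ora_", dir_nm, ".tsv")))
        out[[paste0("n_", dir_nm, "_sets_q05")]] <- sum(tab$q < 0.05)
      }
      out
    })
  }

  if ("interactions" %in% stages) {
    report$stages$interactions <- run_stage("interactions", function() {
      main <- state$differential[[1]]
      if (is.null(state$catalog)) return(list(skipped = "no interaction catalog"))
      categories <- unique(c(names(interaction_categories()),
                             state$catalog$category))
      tab <- map_ligands_to_receptors(main, state$catalog,
                                      selection = config$selection,
                                      q_threshold = th$fdr)
      state$binding <- tab
      write_tsv(as.data.frame(tab), file.path(out_dir, "binding_partners.tsv"))
      pc <- partition_counts(tab, categories = categories)
      write_json_out(list(selection = config$selection,
                          counts = as.list(pc$counts), total = pc$total),
                     file.path(out_dir, "binding_summary.json"))
      hi <- highlight_significant_ligands(tab, th$fdr)
      write_tsv(hi, file.path(out_dir, "binding_partners_significant.tsv"))
      list(total = pc$total, counts = as.list(pc$counts))
    })
  }

  if ("celltargets" %in% stages) {
    report$stages$celltargets <- run_stage("celltargets", function() {
      if (is.null(state$reference)) return(list(skipped = "no reference"))
      receptors <- unique(state$binding$receptor)
      if (!length(receptors)) return(list(skipped = "no mapped receptors"))
      sc <- permutation_null(receptors, state$reference,
                             n_perm = th$n_perm, seed = seed)
      write_tsv(sc, file.path(out_dir, "celltype_enrichment.tsv"))
      top <- sc$cell_type[sc$rank == 1]
      list(top_cell_type = top,
           n_receptors_used = attr(sc, "n_receptors_used"))
    })
  }

  if ("deconvolution" %in% stages) {
    report$stages$deconvolution <- run_stage("deconvolution", function() {
      if (is.null(state$reference) || is.null(state$mixture))
        return(list(skipped = "no reference/mixture"))
      sig <- build_signature_matrix(state$reference, th$n_markers_per_type)
      dec <- nnls_deconvolve(state$mixture$profile, sig)
      write_json_out(list(proportions = as.list(round(dec$proportions, 6)),
                          residual = dec$residual,
                          n_genes_used = dec$n_genes_used),
                     file.path(out_dir, "deconvolution.json"))
      err <- mean(abs(dec$proportions -
                        state$mixture$truth$true_proportions[names(dec$proportions)]))
      list(mean_abs_error = err,
           top_type = names(dec$proportions)[which.max(dec$proportions)])
    })
  }

  if ("biomarker" %in% stages) {
    report$stages$biomarker <- run_stage("biomarker", function() {
      if (is.null(state$readout) || is.null(state$profile))
        return(list(skipped = "no readout/stage profile"))
      rep_tri <- triage(state$filtered, state$readout[colnames(state$filtered$values)],
                        state$profile, alpha = th$alpha,
                        trend_threshold = th$trend)
      write_tsv(rep_tri$correlation, file.path(out_dir, "biomarker_correlation.tsv"))
      if (!is.null(rep_tri$trend))
        write_tsv(rep_tri$trend, file.path(out_dir, "biomarker_trend.tsv"))
      if (!is.null(rep_tri$ranking))
        write_tsv(rep_tri$ranking, file.path(out_dir, "biomarker_ranking.tsv"))
      write_json_out(list(final = rep_tri$final, notes = rep_tri$notes),
                     file.path(out_dir, "biomarker_final.json"))
      list(n_correlated = sum(rep_tri$correlation$retained),
           final = rep_tri$final)
    })
  }

  report$warnings <- warn_log
  if (include_timing)
    report$wall_seconds <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  write_json_out(report, file.path(out_dir, "run_report.json"))
  invisible(report)
}
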