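#' Configuration for the synthetic EV proteome generator
#'
#' Defaults reproduce the study conditions the pipeline was designed around:
#' 4348 identified proteins, 3 donors per group (healthy vs MASH cirrhotic
#' liver slices), each donor incubated in both a standard (WEGG) and a
#' MASLD-mimicking (GFIPO) medium.
#'
#' @param n_proteins Number of proteins to simulate.
#' @param n_donors_per_group Donors per group (>= 2).
#' @param groups Ordered group labels; the second is the "disease" level that
#'   carries the planted effect.
#' @param media Ordered medium labels; the second carries the (sub-detection)
#'   medium effect.
#' @param frac_de Fraction of proteins given a true group effect.
#' @param effect_size_sd Planted group log2 effect in units of the protein's
#'   residual SD.
#' @param missing_rate Overall fraction of cells censored to missing
#'   (left-censoring, concentrated at low intensities).
#' @param peptide_count_range Integer interval (lower bound >= 1) from which
#'   per-protein peptide counts are drawn.
#' @param variance_prior_df Degrees of freedom of the scaled
#'   inverse-chi-square from which residual variances are drawn.
#' @param variance_scale Prior variance scale at peptide count 1; the prior
#'   scale for count c is `variance_scale / c`, so the count-variance trend
#'   the moderation stage fits actually exists in the data.
#' @param medium_effect_sd SD of the (small) per-protein medium effect in
#'   units of the protein's residual SD; the default 0.3 keeps medium
#'   contrasts below detection at n = 3, mirroring the empirical null
#'   result for medium.
#' @param n_biomarkers Number of planted fibrosis-biomarker proteins; they
#'   receive a shared per-sample latent "fibrogenic activity" residual
#'   component (correlation `biomarker_rho`), a positive group effect and a
#'   low residual variance, the profile the triage stage screens for.
#' @param biomarker_rho Residual correlation among planted biomarkers.
#' @param paired If `TRUE` (default) the same donor is incubated in both
#'   media; if `FALSE` donors are distinct per medium.
#' @param seed Non-negative master seed; all generator stages derive named
#'   substreams from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 4348L,
                       n_donors_per_group = 3L,
                       groups = c("healthy", "MASH"),
                       media = c("WEGG", "GFIPO"),
                       frac_de = 0.12,
                       effect_size_sd = 4.5,
                       missing_rate = 0.06,
                       peptide_count_range = c(1L, 40L),
                       variance_prior_df = 4,
                       variance_scale = 0.5,
                       medium_effect_sd = 0.3,
                       n_biomarkers = 2L,
                       biomarker_rho = 0.97,
                       paired = TRUE,
                       seed = 1L) {
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(n_proteins) || n_proteins < 1) stop("n_proteins must be a positive integer")
  if (!num_ok(n_donors_per_group) || n_donors_per_group < 2)
    stop("n_donors_per_group must be >= 2")
  if (length(groups) != 2L || length(media) != 2L)
    stop("exactly two groups and two media are supported")
  for (f in c(frac_de = frac_de, missing_rate = missing_rate)) {
    if (!num_ok(f) || f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  if (!num_ok(effect_size_sd) || effect_size_sd < 0) stop("effect_size_sd must be >= 0")
  if (!num_ok(peptide_count_range) || length(peptide_count_range) != 2L ||
      peptide_count_range[1] < 1 || peptide_count_range[2] < peptide_count_range[1])
    stop("peptide_count_range must be an integer interval with lower bound >= 1")
  if (!num_ok(variance_prior_df) || variance_prior_df <= 0)
    stop("variance_prior_df must be positive")
  if (!num_ok(variance_scale) || variance_scale <= 0)
    stop("variance_scale must be positive")
  if (!num_ok(medium_effect_sd) || medium_effect_sd < 0)
    stop("medium_effect_sd must be >= 0")
  if (!num_ok(biomarker_rho) || biomarker_rho < 0 || biomarker_rho >= 1)
    stop("biomarker_rho must lie in [0, 1)")
  if (!num_ok(n_biomarkers) || n_biomarkers < 0) stop("n_biomarkers must be >= 0")
  if (!num_ok(seed) || seed < 0) stop("seed must be a non-negative integer")
  structure(list(
    n_proteins = as.integer(n_proteins),
    n_donors_per_group = as.integer(n_donors_per_group),
    groups = as.character(groups), media = as.character(media),
    frac_de = frac_de, effect_size_sd = effect_size_sd,
    missing_rate = missing_rate,
    peptide_count_range = as.integer(peptide_count_range),
    variance_prior_df = variance_prior_df, variance_scale = variance_scale,
    medium_effect_sd = medium_effect_sd,
    n_biomarkers = as.integer(n_biomarkers), biomarker_rho = biomarker_rho,
    paired = isTRUE(paired), seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate a log2 EV proteome with recorded ground truth
#'
#' Per protein g, a baseline mean mu_g ~ U(18, 30) (log2 arbitrary units) and
#' a residual variance sigma_g^2 from a scaled inverse-chi-square whose scale
#' decreases with the protein's peptide count. Observed log2 intensity is
#' mu_g + beta_group 1(disease) + beta_medium 1(modified medium) + noise,
#' with beta_group = effect_size_sd * sigma_g (random sign) for the planted
#' fraction and 0 otherwise, and beta_medium small for all proteins. Cells
#' are censored to missing with probability increasing logistically as the
#' intensity falls below its 25% quantile (left-censoring), scaled to the
#' requested overall missing rate.
#'
#' @param config A [sim_config()].
#' @return A list with elements `matrix` (an [ev_matrix()]) and `truth`
#'   (planted effects, biomarker ids, seed used).
#' @export
generate_ev_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(substream_seed(cf$seed, "ev_proteome"))
  n <- cf$n_proteins
  proteins <- sprintf("EVP%05d", seq_len(n))

  donors <- lapply(cf$groups, function(g)
    sprintf("%s%02d", toupper(substr(g, 1, 1)), seq_len(cf$n_donors_per_group)))
  names(donors) <- cf$groups
  dsn <- do.call(rbind, lapply(cf$groups, function(g) {
    do.call(rbind, lapply(cf$media, function(m) {
      ids <- if (cf$paired) donors[[g]] else
        sprintf("%s_%s%02d", toupper(substr(g, 1, 1)), substr(m, 1, 1),
                seq_len(cf$n_donors_per_group))
      data.frame(sample_id = sprintf("%s_%s_%s", g, m, ids),
                 group = g, medium = m, donor_id = ids,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(dsn) <- NULL
  S <- nrow(dsn)
  is_disease <- dsn$group == cf$groups[2]
  is_mod_medium <- dsn$medium == cf$media[2]

  counts <- sample(seq(cf$peptide_count_range[1], cf$peptide_count_range[2]),
                   n, replace = TRUE)
  mu <- runif(n, 18, 30)
  d0 <- cf$variance_prior_df
  sigma2_prior <- cf$variance_scale / counts
  sigma2 <- sigma2_prior * d0 / rchisq(n, df = d0)
  sigma <- sqrt(sigma2)

  n_de <- round(cf$frac_de * n)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)

  # planted biomarkers: positive effect, low residual variance (high peptide
  # count, high abundance) and a shared latent residual so they are mutually
  # correlated -- the profile of a reliably detected fibrosis marker
  n_bio <- min(cf$n_biomarkers, n)
  bio_idx <- integer(0)
  if (n_bio > 0) {
    pool <- if (length(de_idx) >= n_bio && cf$frac_de > 0) de_idx else seq_len(n)
    bio_idx <- sort(sample(pool, n_bio))
    counts[bio_idx] <- cf$peptide_count_range[2]
    sigma2[bio_idx] <- 0.25 * cf$variance_scale / counts[bio_idx]
    sigma <- sqrt(sigma2)
    mu[bio_idx] <- runif(n_bio, 24, 28)
  }

  beta_group <- numeric(n)
  if (n_de > 0)
    beta_group[de_idx] <- cf$effect_size_sd * sigma[de_idx] *
      sample(c(-1, 1), n_de, replace = TRUE)
  if (n_bio > 0 && cf$frac_de > 0)
    beta_group[bio_idx] <- cf$effect_size_sd * sigma[bio_idx]
  beta_medium <- rnorm(n, 0, cf$medium_effect_sd) * sigma

  eps <- matrix(rnorm(n * S), n, S)
  if (n_bio > 0 && cf$biomarker_rho > 0) {
    latent <- rnorm(S)
    eps[bio_idx, ] <- sqrt(cf$biomarker_rho) * matrix(latent, n_bio, S, byrow = TRUE) +
      sqrt(1 - cf$biomarker_rho) * eps[bio_idx, , drop = FALSE]
  }
  x <- mu + outer(beta_group, as.numeric(is_disease)) +
    outer(beta_medium, as.numeric(is_mod_medium)) + sigma * eps
  dimnames(x) <- list(proteins, dsn$sample_id)

  if (cf$missing_rate > 0) {
    q_low <- stats::quantile(x, 0.25)
    sc <- stats::sd(x) / 2
    w <- stats::plogis((q_low - x) / sc)
    p_miss <- pmin(cf$missing_rate * w / mean(w), 1)
    # planted biomarkers emulate consistently detected high-abundance
    # proteins (the triage operates on complete cases), so they are never
    # censored
    if (n_bio > 0) p_miss[bio_idx, ] <- 0
    x[matrix(runif(n * S), n, S) < p_miss] <- NA_real_
  }

  truth <- list(
    de_proteins = stats::setNames(beta_group[de_idx], proteins[de_idx]),
    biomarker_proteins = proteins[bio_idx],
    residual_sd = stats::setNames(sigma, proteins),
    baseline_mean = stats::setNames(mu, proteins),
    medium_effects = stats::setNames(beta_medium, proteins),
    seed_used = cf$seed)
  list(matrix = ev_matrix(x, counts, dsn), truth = truth)
}

#' Default interaction categories and weights
#'
#' The closed category label set of curated ligand-receptor catalogs, with
#' default weights proportional to the reported partition of 271 cognate
#' binding partners (166 adhesion, 38 cytokine-cytokine receptor, 22
#' ECM-receptor, 6 secreted-to-ECM, 39 secreted-to-receptor).
#'
#' @return Named numeric vector of category weights.
#' @export
interaction_categories <- function() {
  c("adhesion" = 166, "cytokine-cytokine receptor" = 38, "ECM-receptor" = 22,
    "secreted-to-ECM" = 6, "secreted-to-receptor" = 39)
}

#' Generate a categorized ligand-receptor interaction catalog
#'
#' @param n_ligands,n_receptors Numbers of distinct ligand and receptor
#'   symbols.
#' @param category_weights Named non-negative weights over categories (not
#'   all zero); defaults to [interaction_categories()].
#' @param seed Integer seed.
#' @param universe Optional protein symbol universe; a fraction
#'   `universe_overlap` of ligands is drawn from it so catalog ligands
#'   overlap the proteome.
#' @param universe_overlap Fraction of ligands drawn from `universe`.
#' @param mean_partners Mean number of receptors per ligand (>= 1).
#' @return Data frame with columns `ligand`, `receptor`, `category`,
#'   `source`; no duplicated (ligand, receptor, category) triples.
#' @export
generate_interaction_catalog <- function(n_ligands, n_receptors,
                                         category_weights = interaction_categories(),
                                         seed = 1L,
                                         universe = NULL,
                                         universe_overlap = 0.6,
                                         mean_partners = 2) {
  if (any(category_weights < 0)) stop("category weights must be non-negative")
  if (all(category_weights == 0)) stop("category weights must not all be zero")
  if (is.null(names(category_weights)))
    stop("category_weights must be named")
  empty <- data.frame(ligand = character(0), receptor = character(0),
                      category = character(0), source = character(0),
                      stringsAsFactors = FALSE)
  if (n_ligands < 1 || n_receptors < 1) return(empty)
  set.seed(substream_seed(seed, "interaction_catalog"))
  n_from_universe <- if (is.null(universe)) 0L else
    min(round(universe_overlap * n_ligands), length(universe), n_ligands)
  ligands <- c(if (n_from_universe > 0) sample(normalize_symbols(universe), n_from_universe),
               if (n_ligands > n_from_universe)
                 sprintf("LGX%04d", seq_len(n_ligands - n_from_universe)))
  receptors <- sprintf("RCPT%04d", seq_len(n_receptors))
  cats <- names(category_weights)
  recs <- do.call(rbind, lapply(ligands, function(lg) {
    k <- min(1 + rpois(1, max(mean_partners - 1, 0)), n_receptors)
    data.frame(ligand = lg,
               receptor = sample(receptors, k),
               category = sample(cats, k, replace = TRUE,
                                 prob = category_weights / sum(category_weights)),
               source = "synthetic", stringsAsFactors = FALSE)
  }))
  recs <- recs[!duplicated(recs[c("ligand", "receptor", "category")]), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

#' Cell-type (or tissue) expression reference
#'
#' @param expression Non-negative numeric matrix, cell types in rows, genes
#'   in columns, both dimnamed.
#' @return Object of class `celltype_reference`.
#' @export
celltype_reference <- function(expression) {
  if (!is.matrix(expression) || !is.numeric(expression))
    stop("expression must be a numeric matrix (cell types x genes)")
  if (any(expression < 0)) stop("expression must be non-negative")
  if (is.null(rownames(expression)) || anyDuplicated(rownames(expression)))
    stop("cell-type labels must be present and unique")
  if (is.null(colnames(expression)) || anyDuplicated(colnames(expression)))
    stop("gene symbols must be present and unique")
  structure(list(expression = expression,
                 cell_types = rownames(expression),
                 genes = colnames(expression)),
            class = "celltype_reference")
}

#' @export
print.celltype_reference <- function(x, ...) {
  cat(sprintf("celltype_reference: %d cell types x %d genes\n",
              length(x$cell_types), length(x$genes)))
  invisible(x)
}

#' Generate a cell-type expression reference with an optional planted
#' receptor-enriched type
#'
#' Base expression is log-normal per (type, gene); for genes in
#' `receptor_set`, expression in `enriched_type` is multiplied by `boost`.
#'
#' @param n_celltypes,n_genes Reference dimensions.
#' @param enriched_type Label of the planted type (must be among the types);
#'   `NULL` for a null reference.
#' @param receptor_set Genes boosted in the enriched type (subset of the gene
#'   universe).
#' @param boost Multiplier > 0; 1 plants nothing.
#' @param seed Integer seed.
#' @param cell_types,gene_symbols Optional label vectors; defaults
#'   `celltype_01..` and `GENE00001..`.
#' @return A list with `reference` (a [celltype_reference()]) and `truth`
#'   (the planted type, or `NULL`).
#' @export
generate_celltype_reference <- function(n_celltypes, n_genes,
                                        enriched_type = NULL,
                                        receptor_set = character(0),
                                        boost = 1, seed = 1L,
                                        cell_types = NULL, gene_symbols = NULL) {
  if (!is.finite(boost) || boost <= 0) stop("boost must be > 0")
  cell_types <- cell_types %||% sprintf("celltype_%02d", seq_len(n_celltypes))
  gene_symbols <- normalize_symbols(gene_symbols %||% sprintf("GENE%05d", seq_len(n_genes)))
  receptor_set <- normalize_symbols(receptor_set)
  if (length(setdiff(receptor_set, gene_symbols)))
    stop("receptor_set must be a subset of the gene universe")
  if (!is.null(enriched_type) && !enriched_type %in% cell_types)
    stop("enriched_type must be one of the cell types")
  set.seed(substream_seed(seed, "celltype_reference"))
  expr <- matrix(rlnorm(n_celltypes * n_genes, meanlog = 1, sdlog = 1),
                 n_celltypes, n_genes, dimnames = list(cell_types, gene_symbols))
  planted <- NULL
  if (!is.null(enriched_type) && boost != 1 && length(receptor_set)) {
    expr[enriched_type, receptor_set] <- expr[enriched_type, receptor_set] * boost
    planted <- enriched_type
  }
  list(reference = celltype_reference(expr),
       truth = list(enriched_cell_type = planted))
}

#' Generate a per-sample fibrosis readout correlated with planted biomarkers
#'
#' Emulates a secreted pro-collagen 1a1 measurement: an affine function of
#' the mean log2 intensity of the biomarker proteins plus noise. By default
#' the noise is orthogonalised in-sample against the biomarker mean and
#' scaled so that the sample correlation of the readout with the biomarker
#' mean equals `target_r / gamma`, where gamma is the mean in-sample
#' correlation of each biomarker with the mean -- so the readout's
#' correlation with each planted biomarker lands near `target_r`.
#'
#' @param matrix An [ev_matrix()].
#' @param biomarkers Protein ids present in `matrix`.
#' @param target_r Target correlation in (-1, 1).
#' @param seed Integer seed.
#' @param noise_sd Optional explicit noise SD (concentration units) that
#'   bypasses the correlation calibration; `0` returns a noiseless affine
#'   transform of the biomarker mean (sample correlation 1).
#' @param base_level,scale Location and scale of the readout (concentration
#'   units, kept positive).
#' @return Named positive numeric vector over samples.
#' @export
generate_fibrosis_readout <- function(matrix, biomarkers, target_r, seed = 1L,
                                      noise_sd = NULL,
                                      base_level = 200, scale = 50) {
  stopifnot(inherits(matrix, "ev_matrix"))
  if (abs(target_r) >= 1) stop("|target_r| must be < 1")
  biomarkers <- normalize_symbols(biomarkers)
  missing_bio <- setdiff(biomarkers, rownames(matrix$values))
  if (length(missing_bio))
    stop("biomarkers absent from matrix: ", paste(missing_bio, collapse = ", "))
  vals <- matrix$values[biomarkers, , drop = FALSE]
  if (anyNA(vals)) stop("biomarker rows contain missing values")
  m <- colMeans(vals)
  S <- length(m)
  if (S < 3) stop("need at least 3 samples")
  set.seed(substream_seed(seed, "fibrosis_readout"))
  if (!is.null(noise_sd)) {
    a <- scale / stats::sd(m)
    y <- base_level + a * (m - mean(m)) + rnorm(S, 0, noise_sd)
  } else if (target_r == 0) {
    y <- base_level + rnorm(S, 0, scale)
  } else {
    gamma <- mean(apply(vals, 1, function(r) stats::cor(m, r)))
    r_m <- max(min(target_r / gamma, 0.99), -0.99)
    zm <- as.numeric(base::scale(m))
    e <- rnorm(S)
    e_perp <- e - zm * sum(e * zm) / sum(zm * zm)
    e_perp <- as.numeric(base::scale(e_perp))
    y <- base_level + scale * (r_m * zm + sqrt(1 - r_m^2) * e_perp)
  }
  stats::setNames(pmax(y, 1), colnames(matrix$values))
}

#' Generate gene expression trajectories across ordered disease stages
#'
#' Genes in `monotone_genes` get strictly increasing stage means; all other
#' genes get exchangeable noise across stages.
#'
#' @param stages Ordered stage labels (>= 3, unique); default is a six-stage
#'   MASLD progression from control through fibrosis stage 4.
#' @param monotone_genes Genes planted with a strictly increasing trend.
#' @param n_genes Total number of genes (ignored when `gene_symbols` given).
#' @param seed Integer seed.
#' @param gene_symbols Optional explicit gene universe.
#' @return Object of class `stage_profile`: list with `means` (genes x
#'   stages), `stages`, `monotone_genes`.
#' @export
generate_stage_trajectories <- function(stages = c("control", "NAFL", "NASH_F0F1",
                                                   "NASH_F2", "NASH_F3", "NASH_F4"),
                                        monotone_genes = character(0),
                                        n_genes = 100L, seed = 1L,
                                        gene_symbols = NULL) {
  if (anyDuplicated(stages)) stop("duplicate stage labels")
  if (length(stages) < 3) stop("need at least 3 ordered stages")
  genes <- normalize_symbols(gene_symbols %||% sprintf("GENE%05d", seq_len(n_genes)))
  monotone_genes <- normalize_symbols(monotone_genes)
  if (length(setdiff(monotone_genes, genes)))
    stop("monotone_genes must be a subset of the gene universe")
  set.seed(substream_seed(seed, "stage_trajectories"))
  G <- length(genes); K <- length(stages)
  means <- matrix(rnorm(G * K, mean = rep(runif(G, 5, 10), K), sd = 1),
                  G, K, dimnames = list(genes, stages))
  if (length(monotone_genes)) {
    for (g in monotone_genes) {
      base <- runif(1, 5, 10)
      means[g, ] <- base + cumsum(c(0, runif(K - 1, 0.3, 1)))
    }
  }
  structure(list(means = means, stages = stages, monotone_genes = monotone_genes),
            class = "stage_profile")
}

#' Mix cell-type reference profiles into a bulk EV-like profile
#'
#' @param reference A [celltype_reference()].
#' @param proportions Simplex vector over the reference's cell types (sums to
#'   1 within 1e-6).
#' @param noise_sd Non-negative additive noise SD; the mixed profile is
#'   truncated at zero.
#' @param seed Integer seed.
#' @return List with `profile` (named non-negative gene vector) and `truth`
#'   (the generating proportions).
#' @export
generate_mixture <- function(reference, proportions, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(reference, "celltype_reference"))
  K <- length(reference$cell_types)
  if (length(proportions) != K)
    stop("proportions length must equal the number of cell types")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-6)
    stop("proportions must be non-negative and sum to 1 (within 1e-6)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(substream_seed(seed, "mixture"))
  profile <- as.numeric(proportions %*% reference$expression)
  if (noise_sd > 0)
    profile <- profile + rnorm(length(profile), 0, noise_sd)
  profile <- pmax(profile, 0)
  names(profile) <- reference$genes
  list(profile = profile,
       truth = list(true_proportions = stats::setNames(proportions, reference$cell_types)))
}

#' Generate EV-catalog-like gene sets covering a protein universe
#'
#' Emulates curated EV protein catalogs (Exocarta/Vesiclepedia-like): each
#' set covers a stated fraction of the query universe plus catalog-only
#' symbols.
#'
#' @param universe Protein symbols.
#' @param coverage Named fractions in \[0, 1\]; one catalog per name.
#' @param n_extra Catalog-only symbols added per set.
#' @param seed Integer seed.
#' @return Named list of symbol sets.
#' @export
generate_catalog_sets <- function(universe,
                                  coverage = c(exocarta = 0.75, vesiclepedia = 0.92),
                                  n_extra = 500L, seed = 1L) {
  if (any(coverage < 0 | coverage > 1)) stop("coverage fractions must lie in [0, 1]")
  universe <- normalize_symbols(universe)
  set.seed(substream_seed(seed, "catalog_sets"))
  out <- lapply(seq_along(coverage), function(i) {
    inside <- sample(universe, round(coverage[i] * length(universe)))
    c(inside, sprintf("CAT%s%05d", toupper(substr(names(coverage)[i], 1, 2)),
                      seq_len(n_extra)))
  })
  names(out) <- names(coverage)
  out
}

#' Generate pathway-like gene sets over a protein universe
#'
#' Random gene sets of varying size for over-representation analysis.
#'
#' @param universe Protein symbols.
#' @param n_sets Number of sets.
#' @param size_range Integer interval of set sizes.
#' @param seed Integer seed.
#' @return Named list of symbol sets.
#' @export
generate_pathway_sets <- function(universe, n_sets = 20L,
                                  size_range = c(20L, 80L), seed = 1L) {
  universe <- normalize_symbols(universe)
  if (size_range[1] < 1 || size_range[2] > length(universe))
    stop("size_range must lie within [1, length(universe)]")
  set.seed(substream_seed(seed, "pathway_sets"))
  out <- lapply(seq_len(n_sets), function(i)
    sample(universe, sample(seq(size_range[1], size_range[2]), 1)))
  names(out) <- sprintf("pathway_%02d", seq_len(n_sets))
  out
}

#' Generate MISEV-style positive/negative EV marker panels
#'
#' Draws small positive (transmembrane/GPI-anchored, cytosolic) and negative
#' (lipoprotein/organelle contaminant) marker sets from (and beyond) a
#' protein universe.
#'
#' @param universe Protein symbols.
#' @param n_per_set Markers per category.
#' @param detected_fraction Fraction of each set drawn from the universe.
#' @param seed Integer seed.
#' @return List with `positive` and `negative`, each a named list of sets.
#' @export
generate_marker_panels <- function(universe, n_per_set = 5L,
                                   detected_fraction = 0.8, seed = 1L) {
  universe <- normalize_symbols(universe)
  set.seed(substream_seed(seed, "marker_panels"))
  draw <- function(tag) {
    n_in <- round(detected_fraction * n_per_set)
    c(sample(universe, n_in),
      if (n_per_set > n_in) sprintf("%s%03d", tag, seq_len(n_per_set - n_in)))
  }
  list(positive = list("transmembrane_GPI" = draw("TMGPI"),
                       "cytosolic" = draw("CYTO")),
       negative = list("lipoprotein" = draw("LIPO"),
                       "organelle" = draw("ORGA")))
}
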