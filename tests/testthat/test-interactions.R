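# ligand-to-receptor mapping, category partition and highlighting

make_diff <- function(ids, effect, q) {
  data.frame(protein_id = ids, effect = effect, q = q,
             stringsAsFactors = FALSE)
}

test_that("mapping fans out ligands over their receptors with annotations", {
  diff_res <- make_diff(c("LGA", "LGB"), c(1.2, -0.4), c(0.01, 0.2))
  catalog <- data.frame(ligand = c("LGA", "LGA", "LGA", "LGC"),
                        receptor = c("R1", "R2", "R3", "R4"),
                        category = "adhesion", source = "x",
                        stringsAsFactors = FALSE)
  tab <- map_ligands_to_receptors(diff_res, catalog, selection = "all")
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$ligand == "LGA"))
  expect_true(all(tab$ligand_effect == 1.2))
  expect_identical(attr(tab, "summary")$total, 3L)

  expect_warning(
    empty <- map_ligands_to_receptors(make_diff("ZZZ", 1, 0.5), catalog,
                                      selection = "all_significant"),
    "no proteins")
  expect_identical(nrow(empty), 0L)
  expect_identical(attr(empty, "summary")$total, 0L)
})

test_that("selection rules behave and enlarging the selection never shrinks counts", {
  ids <- sprintf("LG%02d", 1:10)
  diff_res <- make_diff(ids, effect = c(rep(2, 4), rep(-2, 3), rep(0.5, 3)),
                        q = c(rep(0.01, 7), rep(0.5, 3)))
  catalog <- data.frame(ligand = rep(ids, each = 2),
                        receptor = rep(c("R1", "R2"), 10),
                        category = rep(c("adhesion", "ECM-receptor"), 10),
                        stringsAsFactors = FALSE)
  up <- map_ligands_to_receptors(diff_res, catalog, "upregulated_significant")
  sig <- map_ligands_to_receptors(diff_res, catalog, "all_significant")
  all_tab <- map_ligands_to_receptors(diff_res, catalog, "all")
  expect_identical(attr(up, "summary")$total, 8L)     # 4 up-significant x 2
  expect_identical(attr(sig, "summary")$total, 14L)
  expect_identical(attr(all_tab, "summary")$total, 20L)
  c_up <- partition_counts(up)$counts
  c_sig <- partition_counts(sig)$counts
  c_all <- partition_counts(all_tab)$counts
  expect_true(all(c_sig >= c_up))
  expect_true(all(c_all >= c_sig))
})

test_that("partition counts conserve the total and reject unknown categories", {
  counts_vec <- interaction_categories()           # 166/38/22/6/39 partition
  tab <- data.frame(category = rep(names(counts_vec), times = counts_vec))
  pc <- partition_counts(tab)
  expect_identical(unname(pc$counts), unname(as.integer(counts_vec)))
  expect_identical(pc$total, 271L)
  expect_identical(sum(pc$counts), pc$total)

  expect_identical(partition_counts(data.frame(category = character(0)))$total, 0L)
  ten <- data.frame(category = rep("adhesion", 10))
  expect_identical(unname(partition_counts(ten)$counts), c(10L, 0L, 0L, 0L, 0L))
  expect_error(partition_counts(data.frame(category = "mystery")), "mystery")
})

test_that("highlighting respects the q threshold and effect ordering", {
  tab <- data.frame(ligand = sprintf("L%d", 1:5), receptor = "R",
                    category = "adhesion",
                    ligand_effect = c(0.5, -3, 2, 1, 0.1),
                    ligand_q = c(0.01, 0.01, 0.2, 0.3, 0.04),
                    stringsAsFactors = FALSE)
  hi <- highlight_significant_ligands(tab, 0.05)
  expect_identical(hi$ligand, c("L2", "L1", "L5"))   # |effect| descending
  expect_identical(nrow(highlight_significant_ligands(tab, 0)), 0L)
  expect_identical(nrow(highlight_significant_ligands(tab, 1.0)), 5L)
})

test_that("mapping output is byte-stable across repeated calls", {
  g <- generate_ev_proteome(sim_config(n_proteins = 400, missing_rate = 0, seed = 19))
  res <- ev_differential(g$matrix, within = c(medium = "WEGG"))
  catalog <- generate_interaction_catalog(100, 60, seed = 19,
                                          universe = res$protein_id)
  t1 <- map_ligands_to_receptors(res, catalog, "all")
  t2 <- map_ligands_to_receptors(res, catalog, "all")
  expect_identical(t1, t2)
})

test_that("catalog files round-trip and deduplicate", {
  catalog <- data.frame(ligand = c("a1", "a1", "b2"), receptor = c("r1", "r1", "r2"),
                        category = "adhesion", source = "synthetic",
                        stringsAsFactors = FALSE)
  tmp <- file.path(tempdir(), "catalog.tsv")
  write.table(catalog, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_interaction_catalog(tmp)
  expect_identical(nrow(back), 2L)
  expect_identical(back$ligand, c("A1", "B2"))
})
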