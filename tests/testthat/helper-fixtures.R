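# small hand-built fixtures shared across test files

toy_design <- function(n_per_cell = 1L,
                       groups = c("healthy", "MASH"),
                       media = c("WEGG", "GFIPO")) {
  dsn <- expand.grid(donor = seq_len(n_per_cell), medium = media,
                     group = groups, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%s_%02d", dsn$group, dsn$medium, dsn$donor),
             group = dsn$group, medium = dsn$medium,
             donor_id = sprintf("%s%02d", substr(dsn$group, 1, 1), dsn$donor),
             stringsAsFactors = FALSE)
}

toy_matrix <- function(values, counts = NULL, design = NULL) {
  if (is.null(design)) design <- toy_design()[seq_len(ncol(values)), ]
  colnames(values) <- design$sample_id
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  if (is.null(counts)) counts <- rep(5L, nrow(values))
  ev_matrix(values, counts, design)
}

# two-group matrix: 3 + 3 samples in one medium, used by differential tests
two_group_matrix <- function(values, counts = NULL) {
  dsn <- data.frame(
    sample_id = c(sprintf("healthy_WEGG_%02d", 1:3), sprintf("MASH_WEGG_%02d", 1:3)),
    group = factor(rep(c("healthy", "MASH"), each = 3),
                   levels = c("healthy", "MASH")),
    medium = "WEGG",
    donor_id = sprintf("D%02d", 1:6), stringsAsFactors = FALSE)
  toy_matrix(values, counts, dsn)
}

# independent brute-force BH oracle: min over suffix of sorted p * m / rank
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) min(1, ps[i:m] * (m / (i:m))),
                     numeric(1))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# exact hypergeometric upper tail by combinatorial enumeration
hyper_tail_enum <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
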