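ext_file <- function(name) {
  path <- system.file("extdata", name, package = "proxireg")
  stopifnot(nzchar(path))
  path
}

read_bioid2_fixture <- function() {
  read_count_table(ext_file("bioid2_partners.tsv"), "BIOID2",
                   nuclear_ids = ext_file("nuclear_ids.txt"))
}

read_apex2_fixture <- function() {
  read_count_table(ext_file("apex2_partners.tsv"), "APEX2",
                   nuclear_ids = ext_file("nuclear_ids.txt"))
}

# Random count table for property tests; counts are arbitrary, not planted.
random_count_table <- function(n, max_count = 40, technique = "BIOID2") {
  df <- data.frame(
    gene = paste0("g", seq_len(n)),
    protein_id = paste0("P", seq_len(n)),
    bait1_sham = sample(0:max_count, n, TRUE),
    bait1_20E = sample(0:max_count, n, TRUE),
    bait2_sham = sample(0:max_count, n, TRUE),
    bait2_20E = sample(0:max_count, n, TRUE),
    ctrl_sham = sample(0:5, n, TRUE),
    ctrl_20E = sample(0:5, n, TRUE),
    is_nuclear = sample(c(TRUE, FALSE), n, TRUE, prob = c(0.8, 0.2)))
  count_table(df, technique)
}

# Independent per-record re-evaluation of the selection criteria, written
# as plain scalar arithmetic (the oracle for select_candidates).
brute_force_select <- function(table, min_peptides, min_enrichment,
                               pseudocount, require_nuclear,
                               strict = FALSE) {
  keep <- logical(nrow(table))
  for (i in seq_len(nrow(table))) {
    baits <- c(table$bait1_sham[i], table$bait1_20E[i],
               table$bait2_sham[i], table$bait2_20E[i])
    mc <- max(table$ctrl_sham[i], table$ctrl_20E[i]) + pseudocount
    best <- -Inf
    for (b in baits) {
      r <- if (mc == 0) { if (b > 0) Inf else 0 } else b / mc
      if (r > best) best <- r
    }
    ok <- max(baits) >= min_peptides &&
      (if (strict) best > min_enrichment else best >= min_enrichment)
    if (require_nuclear) ok <- ok && isTRUE(table$is_nuclear[i])
    keep[i] <- ok
  }
  table$protein_id[keep]
}

constant_track <- function(value, nbins = 200, bin_size = 50,
                           chrom = "chrA", kind = "enrichment") {
  cs <- stats::setNames(nbins * bin_size, chrom)
  coverage_track(stats::setNames(list(rep(value, nbins)), chrom),
                 bin_size, cs, kind = kind)
}

# Dense power-law decay matrix by direct element formula (oracle-side
# construction, independent of the simulator).
decay_matrix_oracle <- function(n, alpha = 1, scale = 100) {
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- scale * (abs(i - j) + 1)^(-alpha)
  m
}
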