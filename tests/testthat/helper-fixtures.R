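# Shared fixtures built in code.

# small simulation config for fast tests
small_cfg <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed, n_chromosomes = 1L, chrom_length_bp = 400000L,
    n_cpgs_per_chrom = 2000L, n_planted_tumor_admrs = 10L,
    n_planted_imprinted_regions = 2L, n_planted_random_asm = 2L,
    panel_size = 10L, n_genes = 50L, n_ase_genes = 5L, n_deletions = 100L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# plain call table builder
make_calls <- function(pos, m1, n1, m2, n2, chrom = "chr1") {
  data.table::data.table(
    chrom = chrom, pos = rep(pos, 2), strand = "+",
    haplotype = rep(c("1", "2"), each = length(pos)),
    n_methylated = c(m1, m2), n_total = c(n1, n2))
}

# brute-force O(n*m) interval overlap (half-open)
bf_overlaps <- function(a, b) {
  hits <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j]) {
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov > 0) hits[[length(hits) + 1L]] <- c(i, j, ov)
    }
  }
  if (!length(hits)) return(data.table::data.table(
    a_idx = integer(0), b_idx = integer(0), overlap_bp = integer(0)))
  m <- do.call(rbind, hits)
  data.table::data.table(a_idx = m[, 1], b_idx = m[, 2], overlap_bp = m[, 3])
}

# brute-force distance between half-open intervals (0 when overlapping)
bf_distance <- function(a, b) {
  outer(seq_len(nrow(a)), seq_len(nrow(b)), Vectorize(function(i, j) {
    if (a$chrom[i] != b$chrom[j]) return(Inf)
    if (a$start[i] < b$end[j] && a$end[i] > b$start[j]) return(0)
    max(b$start[j] - a$end[i], a$start[i] - b$end[j])
  }))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 100000L,
                             max_len = 5000L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.table::data.table(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + sample.int(max_len, n, replace = TRUE))
}
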