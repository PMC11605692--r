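test_that("simulation is deterministic and conserves counts", {
  cfg <- small_cfg(seed = 5)
  a <- simulate_phased_methylome(cfg, "tumor")
  b <- simulate_phased_methylome(cfg, "tumor")
  expect_identical(a, b)
  expect_true(all(a$calls$n_methylated <= a$calls$n_total))
  expect_true(all(a$calls$pos >= 0))
  # both strands emitted per CpG and haplotype
  per_site <- a$calls[, .N, by = c("chrom", "pos")]
  expect_true(all(per_site$N == 4L))
})

test_that("truth set lists every planted region exactly once, in bounds", {
  cfg <- small_cfg(seed = 9)
  tr <- simulate_phased_methylome(cfg, "tumor")$truth
  expect_equal(nrow(tr), 14L)
  expect_equal(sum(tr$class == "tumor_specific"), 10L)
  expect_equal(sum(tr$class == "imprinted"), 2L)
  expect_equal(sum(tr$class == "random_asm"), 2L)
  expect_false(any(duplicated(tr[, c("chrom", "start")])))
  expect_true(all(tr$start >= 0 & tr$end <= cfg$chrom_length_bp))
  # regions do not overlap
  data.table::setorder(tr, chrom, start)
  same <- tr$chrom[-1] == tr$chrom[-nrow(tr)]
  expect_true(all(tr$start[-1][same] >= tr$end[-nrow(tr)][same]))
})

test_that("planted allelic delta is recovered from emitted counts", {
  cfg <- small_cfg(seed = 2, mean_coverage_per_haplotype = 30)
  out <- simulate_phased_methylome(cfg, "tumor")
  cons <- merge_strands_to_consensus(out$calls)
  tr <- out$truth[out$truth$class == "tumor_specific"]
  deltas <- vapply(seq_len(nrow(tr)), function(i) {
    s <- cons[cons$chrom == tr$chrom[i] & cons$pos >= tr$start[i] &
                cons$pos < tr$end[i]]
    h1 <- s[s$haplotype == "1"]; h2 <- s[s$haplotype == "2"]
    mean(h1$n_methylated / h1$n_total) - mean(h2$n_methylated / h2$n_total)
  }, numeric(1))
  expect_true(all(abs(deltas - 0.5) < 0.05))
})

test_that("no planted signal means vanishing allelic differences", {
  cfg <- small_cfg(seed = 3, n_planted_tumor_admrs = 0L,
                   n_planted_imprinted_regions = 0L,
                   n_planted_random_asm = 0L,
                   mean_coverage_per_haplotype = 200)
  out <- simulate_phased_methylome(cfg, "tumor")
  expect_equal(nrow(out$truth), 0L)
  cons <- merge_strands_to_consensus(out$calls)
  w <- data.table::dcast(cons, chrom + pos ~ haplotype,
                         value.var = c("n_methylated", "n_total"))
  d <- w$n_methylated_1 / w$n_total_1 - w$n_methylated_2 / w$n_total_2
  expect_lt(mean(abs(d), na.rm = TRUE), 0.05)
})

test_that("tumor-specific regions are background in the normal role", {
  cfg <- small_cfg(seed = 8, mean_coverage_per_haplotype = 60)
  nor <- simulate_phased_methylome(cfg, "normal")
  cons <- merge_strands_to_consensus(nor$calls)
  tr <- nor$truth
  delta_in <- function(klass) {
    r <- tr[tr$class == klass]
    vapply(seq_len(nrow(r)), function(i) {
      s <- cons[cons$chrom == r$chrom[i] & cons$pos >= r$start[i] &
                  cons$pos < r$end[i]]
      h1 <- s[s$haplotype == "1"]; h2 <- s[s$haplotype == "2"]
      mean(h1$n_methylated / h1$n_total) - mean(h2$n_methylated / h2$n_total)
    }, numeric(1))
  }
  expect_true(all(abs(delta_in("tumor_specific")) < 0.1))
  expect_true(all(abs(delta_in("random_asm") - 0.5) < 0.1))
  expect_true(all(abs(delta_in("imprinted")) > 0.7))
})

test_that("panel partial methylation follows the configured fraction", {
  cfg1 <- small_cfg(seed = 4, panel_partial_fraction_at_imprinted = 1)
  truth <- simulate_phased_methylome(cfg1, "tumor")$truth
  imp <- truth[truth$class == "imprinted"]
  in_imp <- function(panel) {
    idx <- rep(FALSE, nrow(panel))
    for (i in seq_len(nrow(imp)))
      idx <- idx | (panel$chrom == imp$chrom[i] & panel$pos >= imp$start[i] &
                      panel$pos < imp$end[i])
    idx
  }
  p1 <- simulate_normal_wgbs_panel(cfg1, truth)
  expect_true(all(p1$frequency[in_imp(p1)] >= 0.35 &
                    p1$frequency[in_imp(p1)] <= 0.65))

  cfg0 <- small_cfg(seed = 4, panel_partial_fraction_at_imprinted = 0)
  p0 <- simulate_normal_wgbs_panel(cfg0, truth)
  expect_false(any(p0$frequency[in_imp(p0)] >= 0.35 &
                     p0$frequency[in_imp(p0)] <= 0.65))

  # empty panel allowed
  pe <- simulate_normal_wgbs_panel(small_cfg(panel_size = 0L), truth)
  expect_equal(nrow(pe), 0L)
})

test_that("per-region partial panel counts are binomial", {
  cfg <- small_cfg(seed = 6, panel_size = 100L,
                   panel_partial_fraction_at_imprinted = 0.05)
  truth <- simulate_phased_methylome(cfg, "tumor")$truth
  panel <- simulate_normal_wgbs_panel(cfg, truth)
  imp <- truth[truth$class == "imprinted"]
  counts <- vapply(seq_len(nrow(imp)), function(i) {
    sub <- panel[panel$chrom == imp$chrom[i] & panel$pos >= imp$start[i] &
                   panel$pos < imp$end[i]]
    partial <- sub[sub$frequency >= 0.35 & sub$frequency <= 0.65]
    length(unique(partial$sample_id))
  }, numeric(1))
  # each count ~ Binomial(100, 0.05); all within a generous tail bound
  expect_true(all(counts >= qbinom(0.0005, 100, 0.05) &
                    counts <= qbinom(0.9995, 100, 0.05)))
})

test_that("allelic expression simulation matches its stated structure", {
  # ase_maf = 0.5 plants nothing
  cfg_null <- small_cfg(seed = 3, ase_maf = 0.5)
  expect_equal(nrow(simulate_allelic_expression(cfg_null)$truth), 0L)

  cfg <- small_cfg(seed = 3)
  ex <- simulate_allelic_expression(cfg)
  expect_equal(nrow(ex$truth), 5L)
  expect_true(all(ex$snv_counts$hap1_reads + ex$snv_counts$hap2_reads >= 1L))
  snps_per_gene <- ex$snv_counts[, .N, by = "gene_id"]$N
  expect_true(all(snps_per_gene >= 1L & snps_per_gene <= 10L))
  # TPM straddles the threshold
  expect_gt(sum(ex$tpm$tpm < 1), 0L)
  expect_gt(sum(ex$tpm$tpm >= 1), 0L)
})

test_that("null gene MAF tail matches the exact binomial oracle", {
  cfg <- sim_config(seed = 12, n_genes = 1000L, n_ase_genes = 0L,
                    reads_per_ase_gene = 100L)
  ex <- simulate_allelic_expression(cfg)
  g <- aggregate_gene_counts(ex$snv_counts)
  observed <- mean(g$maf > 0.65)
  # exact conditional oracle: per gene, Pr(MAF > 0.65 | total) by direct
  # tail summation of Binomial(total, 0.5)
  tail_pr <- vapply(g$H1 + g$H2, function(n) {
    k <- ceiling(0.65 * n + 1e-9)
    if (0.65 * n == floor(0.65 * n)) k <- as.integer(0.65 * n) + 1L
    sum(dbinom(k:n, n, 0.5)) + sum(dbinom(0:(n - k), n, 0.5))
  }, numeric(1))
  expected <- mean(tail_pr)
  se <- sqrt(sum(tail_pr * (1 - tail_pr))) / length(tail_pr)
  expect_lt(abs(observed - expected), 4 * se + 1e-6)
})

test_that("CN segments tile chromosomes and hit the LOH fraction", {
  cfg0 <- small_cfg(seed = 5, loh_fraction_of_genome = 0)
  seg0 <- simulate_cn_segments(cfg0)
  expect_false(any(seg0$minor_cn == 0L))

  cfg <- small_cfg(seed = 5, loh_fraction_of_genome = 0.3)
  seg <- simulate_cn_segments(cfg)
  for (ch in unique(seg$chrom)) {
    d <- seg[seg$chrom == ch]
    expect_equal(d$start[1], 0L)
    expect_equal(d$end[nrow(d)], cfg$chrom_length_bp)
    if (nrow(d) > 1L) expect_equal(d$start[-1], d$end[-nrow(d)])
  }
  loh_frac <- sum((seg$end - seg$start)[seg$minor_cn == 0L]) /
    sum(seg$end - seg$start)
  expect_lt(abs(loh_frac - 0.3), 0.02)
  expect_true(all(seg$major_cn >= seg$minor_cn))
})

test_that("deletion simulation plants exact microhomology", {
  cfg0 <- small_cfg(seed = 7, mh_deletion_fraction_true = 0)
  d0 <- simulate_deletions_with_flanks(cfg0)
  expect_equal(microhomology_deletion_fraction(d0), 0)

  cfg <- small_cfg(seed = 7, n_deletions = 500L,
                   mh_deletion_fraction_true = 0.4)
  d <- simulate_deletions_with_flanks(cfg)
  expect_equal(nrow(d), 500L)
  expect_true(all(nchar(d$deleted_seq) == d$end - d$start))
  expect_true(all(nchar(d$left_flank) >= 10L & nchar(d$right_flank) >= 10L))
  mh <- microhomology_length(d$deleted_seq, d$left_flank, d$right_flank)
  expect_identical(mh, d$planted_mh_len)
})

test_that("impossible packing raises an explicit error", {
  expect_error(
    simulate_phased_methylome(
      small_cfg(n_cpgs_per_chrom = 300L, n_planted_tumor_admrs = 10L),
      "tumor"),
    "packing")
})

test_that("fixture bundle writes readable files", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg(seed = 1, n_cpgs_per_chrom = 600L,
                   n_planted_tumor_admrs = 2L,
                   n_planted_imprinted_regions = 1L,
                   n_planted_random_asm = 0L, panel_size = 2L,
                   n_genes = 10L, n_ase_genes = 2L, n_deletions = 20L)
  paths <- write_sim_bundle(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))
  back <- read_cpg_calls(file.path(dir, "tumor_calls.tsv"))
  expect_gt(nrow(back), 0L)
})
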