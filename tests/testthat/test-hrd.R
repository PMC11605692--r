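test_that("microhomology length matches constructed and no-homology cases", {
  expect_equal(microhomology_length("ACGT", "GGGGGGGGGGGG", "ACTTGGGGGGGG"),
               2L)
  expect_equal(microhomology_length("TTTT", "GGGGGGGGGGGG", "CCCCCCCCCCCC"),
               0L)
  # left-flank suffix homology
  expect_equal(microhomology_length("AACGT", "GGGGGGGGGACGT", "TTTTTTTTTTTT"),
               4L)
  # capped at deletion length
  expect_equal(microhomology_length("AC", "GGGGGGGGGGAC", "ACACACACACAC"),
               2L)
})

test_that("microhomology length equals the brute-force all-k scan", {
  set.seed(47)
  bf_mh <- function(del, lf, rf) {
    L <- nchar(del)
    best <- 0L
    for (k in seq_len(L)) {
      if (k <= nchar(rf) &&
          substr(del, 1, k) == substr(rf, 1, k)) best <- max(best, k)
      if (k <= nchar(lf) &&
          substr(del, L - k + 1, L) ==
            substr(lf, nchar(lf) - k + 1, nchar(lf))) best <- max(best, k)
    }
    best
  }
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
  for (i in 1:200) {
    del <- rand_seq(sample(1:15, 1))  # short alphabet-4 strings collide often
    lf <- rand_seq(12); rf <- rand_seq(12)
    expect_equal(microhomology_length(del, lf, rf), bf_mh(del, lf, rf))
  }
})

test_that("microhomology deletion fraction arithmetic and edge cases", {
  mk <- function(del, rf) data.table::data.table(
    deleted_seq = del, left_flank = strrep("G", 12), right_flank = rf)
  # 10 deletions, 4 long with homology -> 0.4
  d <- rbind(mk(strrep("ACGT", 2), paste0("ACGT", strrep("T", 8)))[rep(1, 4)],
             mk("TTTTTT", strrep("C", 12))[rep(1, 6)])
  expect_equal(microhomology_deletion_fraction(d), 0.4)
  # denominator switch: only >3 bp deletions
  d2 <- rbind(d, mk("A", strrep("C", 12)))
  expect_equal(microhomology_deletion_fraction(d2, denominator = "gt3bp"),
               0.4)
  # all deletions <= 3 bp -> 0 with warning
  d3 <- mk("ACG", strrep("T", 12))
  expect_warning(f <- microhomology_deletion_fraction(d3), "3 bp")
  expect_equal(f, 0)
})

test_that("planted microhomology fraction is recovered within binomial CI", {
  cfg <- sim_config(seed = 53, n_deletions = 500L,
                    mh_deletion_fraction_true = 0.4)
  d <- simulate_deletions_with_flanks(cfg)
  f <- microhomology_deletion_fraction(d)
  ci <- qbinom(c(0.025, 0.975), 500L, 0.4) / 500
  expect_gte(f, ci[1])
  expect_lte(f, ci[2])
})

test_that("scar scores match definitions on constructed genomes", {
  kar <- data.table::data.table(chrom = c("chr1", "chr2"), length = 100e6,
                                centromere = 50e6)
  # single balanced segment per chromosome
  flat <- data.table::data.table(chrom = c("chr1", "chr2"), start = 0L,
                                 end = 100e6, major_cn = 1L, minor_cn = 1L)
  expect_equal(scar_scores(flat, kar), list(loh = 0L, tai = 0L, lst = 0L))

  # one 20 Mb interstitial (2,0) segment: LOH 1; the flanks are balanced
  one_loh <- data.table::data.table(
    chrom = "chr1", start = c(0, 30e6, 50e6), end = c(30e6, 50e6, 100e6),
    major_cn = c(1L, 2L, 1L), minor_cn = c(1L, 0L, 1L))
  s <- scar_scores(one_loh, kar[1])
  expect_equal(s$loh, 1L)
  expect_equal(s$tai, 0L)  # interstitial, reaches no chromosome end

  # telomeric imbalance not crossing the centromere: TAI 1
  tai_seg <- data.table::data.table(
    chrom = "chr1", start = c(0, 30e6), end = c(30e6, 100e6),
    major_cn = c(2L, 1L), minor_cn = c(1L, 1L))
  expect_equal(scar_scores(tai_seg, kar[1])$tai, 1L)

  # same imbalance crossing the centromere: no TAI
  cross <- data.table::data.table(
    chrom = "chr1", start = c(0, 60e6), end = c(60e6, 100e6),
    major_cn = c(2L, 1L), minor_cn = c(1L, 1L))
  expect_equal(scar_scores(cross, kar[1])$tai, 0L)

  # whole-chromosome LOH does not count
  whole <- data.table::data.table(chrom = "chr1", start = 0L, end = 100e6,
                                  major_cn = 1L, minor_cn = 0L)
  expect_equal(scar_scores(whole, kar[1])$loh, 0L)

  # two >=10 Mb arms-worth of segments meeting at a breakpoint: LST counts
  lst_seg <- data.table::data.table(
    chrom = "chr1", start = c(0, 20e6, 50e6, 80e6),
    end = c(20e6, 50e6, 80e6, 100e6),
    major_cn = c(1L, 2L, 1L, 2L), minor_cn = 1L)
  # p arm: 0-20-50 clipped at 50: breakpoint at 20 (20 Mb / 30 Mb): 1
  # q arm: 50-80-100: breakpoint at 80 (30 Mb / 20 Mb): 1
  expect_equal(scar_scores(lst_seg, kar[1])$lst, 2L)

  # small-segment smoothing: a 2 Mb insert between large equal segments
  smooth_seg <- data.table::data.table(
    chrom = "chr1", start = c(0, 24e6, 26e6), end = c(24e6, 26e6, 50e6),
    major_cn = c(1L, 3L, 1L), minor_cn = 1L)
  smooth_seg <- rbind(smooth_seg, data.table::data.table(
    chrom = "chr1", start = 50e6, end = 100e6, major_cn = 1L,
    minor_cn = 1L))
  # after absorbing the 2 Mb segment the arm is uniform: no LST
  expect_equal(scar_scores(smooth_seg, kar[1])$lst, 0L)
})

test_that("scar scores equal an independent direct scan on random genomes", {
  oracle_scars <- function(segs, kar, loh_min = 15e6, lst_min = 10e6) {
    # independent re-implementation: plain loops over merged segments
    merged <- list()
    for (ch in unique(segs$chrom)) {
      d <- as.data.frame(segs[segs$chrom == ch])
      d <- d[order(d$start), ]
      i <- 1L
      while (i < nrow(d)) {
        if (d$major_cn[i] == d$major_cn[i + 1] &&
            d$minor_cn[i] == d$minor_cn[i + 1]) {
          d$end[i] <- d$end[i + 1]; d <- d[-(i + 1), ]
        } else i <- i + 1L
      }
      merged[[ch]] <- d
    }
    loh <- tai <- lst <- 0L
    for (ch in names(merged)) {
      d <- merged[[ch]]
      k <- kar[kar$chrom == ch, ]
      for (r in seq_len(nrow(d))) {
        len <- d$end[r] - d$start[r]
        whole <- d$start[r] <= 0 && d$end[r] >= k$length
        if (d$minor_cn[r] == 0 && len > loh_min && !whole) loh <- loh + 1L
        if (d$major_cn[r] != d$minor_cn[r] && !whole &&
            (d$start[r] <= 0 || d$end[r] >= k$length) &&
            !(d$start[r] < k$centromere && d$end[r] > k$centromere))
          tai <- tai + 1L
      }
      for (arm in list(c(0, k$centromere), c(k$centromere, k$length))) {
        a <- d[d$end > arm[1] & d$start < arm[2], ]
        if (nrow(a) < 2) next
        a$start <- pmax(a$start, arm[1]); a$end <- pmin(a$end, arm[2])
        alen <- a$end - a$start
        for (r in seq_len(nrow(a) - 1))
          if (alen[r] >= lst_min && alen[r + 1] >= lst_min) lst <- lst + 1L
      }
    }
    list(loh = loh, tai = tai, lst = lst)
  }
  for (seed in 1:10) {
    set.seed(seed)
    kar <- data.table::data.table(chrom = "chr1", length = 100e6,
                                  centromere = 45e6)
    # random tiling with all segments >= 10 Mb so smoothing is a no-op in
    # both implementations (the hand-built cases above cover smoothing)
    cuts <- sort(sample(seq(12e6, 88e6, by = 12e6),
                        sample(2:5, 1)))
    bounds <- c(0, cuts, 100e6)
    segs <- data.table::data.table(
      chrom = "chr1", start = bounds[-length(bounds)], end = bounds[-1],
      major_cn = sample(1:3, length(bounds) - 1, TRUE),
      minor_cn = sample(0:1, length(bounds) - 1, TRUE))
    segs$major_cn <- pmax(segs$major_cn, segs$minor_cn)
    expect_equal(scar_scores(segs, kar), oracle_scars(segs, kar))
  }
})

test_that("scar scores are invariant under state-preserving subdivision", {
  kar <- data.table::data.table(chrom = "chr1", length = 100e6,
                                centromere = 50e6)
  segs <- data.table::data.table(
    chrom = "chr1", start = c(0, 30e6, 62e6), end = c(30e6, 62e6, 100e6),
    major_cn = c(2L, 1L, 2L), minor_cn = c(0L, 1L, 1L))
  split_segs <- data.table::data.table(
    chrom = "chr1",
    start = c(0, 10e6, 30e6, 62e6, 70e6), end = c(10e6, 30e6, 62e6, 70e6,
                                                  100e6),
    major_cn = c(2L, 2L, 1L, 2L, 2L), minor_cn = c(0L, 0L, 1L, 1L, 1L))
  expect_equal(scar_scores(segs, kar), scar_scores(split_segs, kar))
})

test_that("hrd index sums the three scores", {
  expect_equal(hrd_index(list(loh = 0L, tai = 0L, lst = 0L)), 0L)
  expect_equal(hrd_index(list(loh = 5L, tai = 7L, lst = 11L)), 23L)
  set.seed(59)
  for (i in 1:100) {
    s <- list(loh = sample(0:30, 1), tai = sample(0:30, 1),
              lst = sample(0:30, 1))
    expect_equal(hrd_index(s), s$loh + s$tai + s$lst)
  }
})

test_that("feature standardization is ln(x+1) then z, with guards", {
  set.seed(61)
  feats <- data.table::data.table(
    sbs3 = c(120, 0, 40, 300, 15), sbs8 = c(10, 20, 5, 80, 40),
    sv3 = c(3, 9, 0, 25, 12), sv5 = c(1, 4, 7, 2, 0),
    hrd_index = c(30, 2, 11, 55, 8), mh_del_fraction = c(0.5, 0.05, 0.2,
                                                         0.45, 0.1))
  z <- standardize_features(feats)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-10)
  # hand recompute one column
  lx <- log(feats$sbs3 + 1)
  expect_lt(max(abs(z[, "sbs3"] - (lx - mean(lx)) / sd(lx))), 1e-10)

  # zero-variance feature
  feats2 <- data.table::copy(feats)
  feats2$sv5 <- 3
  expect_warning(z2 <- standardize_features(feats2), "zero-variance")
  expect_true(all(z2[, "sv5"] == 0))

  # external moments mode
  z3 <- standardize_features(feats, center = setNames(rep(0, 6),
                                                      colnames(z)),
                             scale = setNames(rep(1, 6), colnames(z)))
  expect_equal(z3[, "sbs8"], log(feats$sbs8 + 1))
})

test_that("hrdetect score evaluates the printed logistic model", {
  expect_equal(hrdetect_score(rep(0, 6)), 1 / (1 + exp(3.364)),
               tolerance = 1e-12)
  # monotone limit in the microhomology feature
  z <- rep(0, 6)
  z[6] <- 50
  expect_gt(hrdetect_score(z), 0.999999)
  # strictly increasing in every feature
  set.seed(67)
  for (i in 1:100) {
    z0 <- rnorm(6)
    s0 <- hrdetect_score(z0)
    for (j in 1:6) {
      z1 <- z0; z1[j] <- z1[j] + 0.1
      expect_gt(hrdetect_score(z1), s0)
    }
  }
  expect_true(all(hrdetect_score(matrix(rnorm(60), ncol = 6)) > 0))
  expect_true(all(hrdetect_score(matrix(rnorm(60), ncol = 6)) < 1))
})

test_that("HRD-high classification uses >= 0.7", {
  expect_equal(classify_hrd_high(c(0.70, 0.6999, 0.999)),
               c("high", "not_high", "high"))
})

test_that("promoter methylation fraction applies the mean + 1 SD rule", {
  prom <- data.table::data.table(chrom = "chr1", start = 0L, end = 2000L,
                                 gene_id = "BRCA1")
  pos <- seq_len(20L) * 50L
  # full separation
  tum <- data.table::data.table(chrom = "chr1", pos = pos, frequency = 0.95)
  nrm <- data.table::data.table(chrom = "chr1", pos = pos, mean = 0.05,
                                sd = 0.05)
  r <- promoter_methylation_fraction(prom, tum, nrm)
  expect_equal(r$fraction_methylated_sites, 1)

  # tumor equal to normal mean: nothing methylated
  tum2 <- data.table::data.table(chrom = "chr1", pos = pos, frequency = 0.05)
  expect_equal(promoter_methylation_fraction(prom, tum2,
                                             nrm)$fraction_methylated_sites,
               0)

  # exactly 13 of 20 sites exceed mean + SD
  tum3 <- data.table::data.table(
    chrom = "chr1", pos = pos,
    frequency = c(rep(0.5, 13), rep(0.09, 7)))
  r3 <- promoter_methylation_fraction(prom, tum3, nrm)
  expect_equal(r3$fraction_methylated_sites, 0.65)
  expect_equal(r3$n_sites, 20L)

  # LOH status from segments
  segs <- data.table::data.table(chrom = "chr1", start = 0L, end = 10000L,
                                 major_cn = 2L, minor_cn = 0L)
  r4 <- promoter_methylation_fraction(prom, tum, nrm, segments = segs)
  expect_equal(r4$loh_status, "LOH")
})

test_that("HRD-like samples outrank HR-proficient ones", {
  wins <- vapply(1:20, function(seed) {
    cfg_hrd <- small_cfg(seed = seed, loh_fraction_of_genome = 0.5,
                         mh_deletion_fraction_true = 0.5)
    cfg_pro <- small_cfg(seed = seed + 1000L, loh_fraction_of_genome = 0.05,
                         mh_deletion_fraction_true = 0.05)
    kar <- data.table::data.table(
      chrom = "chr1", length = cfg_hrd$chrom_length_bp,
      centromere = cfg_hrd$chrom_length_bp %/% 2L)
    sc <- cfg_hrd$chrom_length_bp / 1e8
    feat <- function(cfg, sbs3, sbs8, sv3, sv5) {
      segs <- simulate_cn_segments(cfg)
      dels <- simulate_deletions_with_flanks(cfg)
      s <- scar_scores(segs, kar, loh_min_len = 15e6 * sc,
                       lst_min_len = 10e6 * sc, lst_smooth_len = 3e6 * sc)
      data.table::data.table(
        sbs3 = sbs3, sbs8 = sbs8, sv3 = sv3, sv5 = sv5,
        hrd_index = hrd_index(s),
        mh_del_fraction = microhomology_deletion_fraction(dels))
    }
    feats <- rbind(feat(cfg_hrd, sbs3 = 250, sbs8 = 35, sv3 = 20, sv5 = 9),
                   feat(cfg_pro, sbs3 = 20, sbs8 = 25, sv3 = 2, sv5 = 6))
    s <- hrdetect_score(suppressWarnings(standardize_features(feats)))
    s[1] > s[2]
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
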