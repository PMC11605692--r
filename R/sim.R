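# Synthetic phased tumor/normal methylomes with planted ground truth, plus
# normal WGBS panel, allelic RNA counts, copy-number segments and deletions.
#
# Everything derives deterministically from the config seed. The "world"
# (CpG positions, background frequencies, planted regions) is shared between
# the tumor and normal roles so matched-normal filtering is meaningful; only
# the read-sampling noise differs per role.

#' Simulation configuration
#'
#' Defaults describe the regime the rest of the package is tested in:
#' two 1 Mb chromosomes with 5,000 CpGs each, 30x coverage per haplotype
#' (split evenly over the two strands), 50 planted tumor-specific aDMRs of
#' 20 CpGs at allelic delta 0.5, a handful of imprinted and constitutive
#' random-ASM regions, a 30-sample normal WGBS panel that is partially
#' methylated at every imprinted locus, 200 genes with phased allelic RNA
#' counts of which 20 carry true ASE at major-allele frequency 0.8, 30% of
#' the genome under LOH, and 500 deletions of which 40% carry planted
#' breakpoint microhomology.
#'
#' @param seed integer; fixes every downstream draw.
#' @param n_chromosomes,chrom_length_bp,n_cpgs_per_chrom genome shape.
#' @param mean_coverage_per_haplotype Poisson mean of reads per haplotype
#'   (half per strand).
#' @param n_planted_tumor_admrs,n_planted_imprinted_regions,n_planted_random_asm
#'   number of planted regions per class.
#' @param admr_delta allelic methylation difference planted in aDMRs.
#' @param admr_width_cpgs CpGs per planted region.
#' @param panel_size number of normal WGBS panel samples.
#' @param panel_partial_fraction_at_imprinted fraction of panel samples
#'   partially methylated at each imprinted region.
#' @param panel_depth_ge5_fraction fraction of panel CpGs with depth >= 5.
#' @param n_genes,n_ase_genes genes simulated / genes with true ASE.
#' @param ase_maf true major-allele frequency of ASE genes.
#' @param reads_per_ase_gene mean phased RNA reads per gene.
#' @param ase_trans_fraction fraction of ASE genes whose hypermethylated
#'   promoter haplotype is the minor expressed one (methylation silencing,
#'   i.e. trans).
#' @param loh_fraction_of_genome fraction of total genome length with
#'   minor copy number 0.
#' @param n_deletions deletions simulated.
#' @param mh_deletion_fraction_true fraction of deletions constructed with
#'   breakpoint microhomology (those are forced > 3 bp).
#' @return A validated config list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length_bp = 1000000L,
                       n_cpgs_per_chrom = 5000L,
                       mean_coverage_per_haplotype = 30,
                       n_planted_tumor_admrs = 50L,
                       n_planted_imprinted_regions = 5L,
                       n_planted_random_asm = 5L,
                       admr_delta = 0.5,
                       admr_width_cpgs = 20L,
                       panel_size = 30L,
                       panel_partial_fraction_at_imprinted = 1.0,
                       panel_depth_ge5_fraction = 0.95,
                       n_genes = 200L,
                       n_ase_genes = 20L,
                       ase_maf = 0.8,
                       reads_per_ase_gene = 200L,
                       ase_trans_fraction = 0.75,
                       loh_fraction_of_genome = 0.3,
                       n_deletions = 500L,
                       mh_deletion_fraction_true = 0.4) {
  cfg <- as.list(environment())
  fracs <- c("admr_delta", "panel_partial_fraction_at_imprinted",
             "panel_depth_ge5_fraction", "ase_maf", "ase_trans_fraction",
             "loh_fraction_of_genome", "mh_deletion_fraction_true")
  for (f in fracs) {
    .assert(cfg[[f]] >= 0 && cfg[[f]] <= 1, "%s must be in [0,1]", f)
  }
  counts <- c("n_chromosomes", "chrom_length_bp", "n_cpgs_per_chrom",
              "n_planted_tumor_admrs", "n_planted_imprinted_regions",
              "n_planted_random_asm", "admr_width_cpgs", "panel_size",
              "n_genes", "n_ase_genes", "reads_per_ase_gene", "n_deletions")
  for (f in counts) .assert(cfg[[f]] >= 0, "%s must be >= 0", f)
  .assert(cfg$mean_coverage_per_haplotype >= 0, "coverage must be >= 0")
  .assert(cfg$n_ase_genes <= cfg$n_genes, "n_ase_genes > n_genes")
  .assert(cfg$ase_maf >= 0.5, "ase_maf below 0.5 is a relabeling; use >= 0.5")
  structure(cfg, class = "sim_config")
}

# Shared deterministic world: CpG positions, background per-site methylation,
# planted region placement with classes and imprinted haplotype choice.
#
# Background per-CpG methylation is a bimodal Beta mixture (half Beta(0.5,10),
# half Beta(10,0.5)): most CpGs are near-unmethylated or near-methylated on
# both haplotypes, as in real genomes. Planted aDMRs shift the haplotype-1
# mean away from the background value by admr_delta (upward when background
# <= 0.5, downward otherwise, so the realized delta is exact).
.sim_world <- function(config) {
  .with_seed(.child_seed(config$seed, "world"), {
    chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
    width <- config$admr_width_cpgs
    n_regions_total <- config$n_planted_tumor_admrs +
      config$n_planted_imprinted_regions + config$n_planted_random_asm
    # stratified placement: one region per equal-sized CpG-index slot, with a
    # margin of `gap` CpGs on both sides so planted regions stay well clear
    # of each other (in particular, outside the 10 kb imprinting window of a
    # neighboring planted region at default CpG density)
    gap <- 35L
    regions_per_chrom <- ceiling(n_regions_total / config$n_chromosomes)
    if (n_regions_total > 0L) {
      slot <- config$n_cpgs_per_chrom %/% regions_per_chrom
      .assert(slot >= width + 2L * gap + 1L,
              "impossible packing: %d regions of %d CpGs do not fit in %d CpGs",
              n_regions_total, width,
              config$n_cpgs_per_chrom * config$n_chromosomes)
    }

    sites <- list(); regions <- list()
    classes <- c(rep("tumor_specific", config$n_planted_tumor_admrs),
                 rep("imprinted", config$n_planted_imprinted_regions),
                 rep("random_asm", config$n_planted_random_asm))
    if (length(classes)) classes <- sample(classes)  # interleave across genome
    per_chrom <- if (length(classes))
      split(classes, rep_len(seq_along(chroms), length(classes))) else list()

    for (ci in seq_along(chroms)) {
      n <- config$n_cpgs_per_chrom
      pos <- sort(sample.int(config$chrom_length_bp %/% 2L - 1L, n)) * 2L
      base <- ifelse(runif(n) < 0.5, rbeta(n, 0.5, 10), rbeta(n, 10, 0.5))
      cls <- per_chrom[[as.character(ci)]] %||% character(0)

      # one region per slot, uniform within the slot's admissible range
      starts <- integer(0)
      if (length(cls)) {
        slot <- n %/% regions_per_chrom
        slots <- sample(seq_len(regions_per_chrom), length(cls))
        starts <- vapply(slots, function(j) {
          lo <- (j - 1L) * slot + gap + 1L
          hi <- j * slot - width - gap
          as.integer(lo + sample.int(hi - lo + 1L, 1L) - 1L)
        }, integer(1))
      }

      h1 <- base; h2 <- base
      reg <- data.table::data.table(
        chrom = character(0), start = integer(0), end = integer(0),
        class = character(0), imprinted_hap = character(0))
      for (k in seq_along(cls)) {
        idx <- starts[k]:(starts[k] + width - 1L)
        klass <- cls[k]
        ih <- NA_character_
        if (klass == "imprinted") {
          ih <- sample(c("1", "2"), 1L)
          hi <- runif(width, 0.90, 0.98); lo <- runif(width, 0.02, 0.10)
          if (ih == "1") { h1[idx] <- hi; h2[idx] <- lo }
          else { h1[idx] <- lo; h2[idx] <- hi }
        } else {
          # allelic methylation gain: planted regions sit on an unmethylated
          # background (low mixture component) and haplotype 1 gains
          # admr_delta uniformly, so the realized region delta is exact
          base[idx] <- rbeta(width, 0.5, 10)
          h2[idx] <- base[idx]
          h1[idx] <- pmin(base[idx] + config$admr_delta, 1)
        }
        reg <- rbind(reg, data.table::data.table(
          chrom = chroms[ci], start = pos[idx[1]],
          end = pos[idx[width]] + 2L, class = klass, imprinted_hap = ih))
      }
      sites[[ci]] <- data.table::data.table(
        chrom = chroms[ci], pos = pos, base = base, h1 = h1, h2 = h2,
        in_region = seq_len(n) %in% unlist(lapply(seq_along(cls), function(k)
          starts[k]:(starts[k] + width - 1L))),
        region_class = {
          rc <- rep(NA_character_, n)
          for (k in seq_along(cls))
            rc[starts[k]:(starts[k] + width - 1L)] <- cls[k]
          rc
        })
      regions[[ci]] <- reg
    }
    list(sites = data.table::rbindlist(sites),
         regions = data.table::rbindlist(regions),
         chroms = chroms)
  })
}

#' Simulate a phased methylome (tumor or normal role)
#'
#' Emits per-CpG, per-haplotype, per-strand methylation calls. Per strand
#' and haplotype the read total is Poisson(mean_coverage_per_haplotype / 2)
#' and the methylated count is Binomial(total, site frequency). The site
#' frequency is shared between haplotypes for background CpGs; planted
#' regions behave by class: `tumor_specific` differs between haplotypes in
#' the tumor role only, `random_asm` in both roles, `imprinted` has one
#' near-fully methylated haplotype in both roles.
#'
#' @param config a [sim_config()].
#' @param role "tumor" or "normal".
#' @return list(calls = strand-level call table, truth = truth set with
#'   planted regions (chrom, start, end, class)).
#' @export
simulate_phased_methylome <- function(config, role = c("tumor", "normal")) {
  role <- match.arg(role)
  world <- .sim_world(config)
  s <- world$sites
  h1 <- s$h1; h2 <- s$h2
  if (role == "normal") {
    # tumor-specific regions are background-identical in the normal
    ts <- !is.na(s$region_class) & s$region_class == "tumor_specific"
    h1[ts] <- s$base[ts]; h2[ts] <- s$base[ts]
  }
  n <- nrow(s)
  lam <- config$mean_coverage_per_haplotype / 2
  calls <- .with_seed(.child_seed(config$seed, paste0("counts_", role)), {
    grid <- data.table::CJ(i = seq_len(n), haplotype = c("1", "2"),
                           strand = c("+", "-"), sorted = FALSE)
    freq <- ifelse(grid$haplotype == "1", h1[grid$i], h2[grid$i])
    tot <- rpois(nrow(grid), lam)
    met <- rbinom(nrow(grid), tot, freq)
    data.table::data.table(
      chrom = s$chrom[grid$i], pos = s$pos[grid$i], strand = grid$strand,
      haplotype = grid$haplotype, n_methylated = met, n_total = tot)
  })
  data.table::setorder(calls, chrom, pos, haplotype, strand)
  truth <- world$regions[, c("chrom", "start", "end", "class")]
  list(calls = calls[], truth = truth[])
}

#' Simulate a normal WGBS methylation-frequency panel
#'
#' Each panel sample reports a consensus methylation frequency and depth per
#' CpG of the shared simulated CpG grid. At imprinted-region CpGs a sample is
#' partially methylated (frequency drawn in [0.40, 0.60]) with probability
#' `panel_partial_fraction_at_imprinted`, decided once per (sample, region).
#' Elsewhere frequencies track the bimodal background with small noise, so
#' they stay outside the partial band. Depth is >= 5 at
#' `panel_depth_ge5_fraction` of sites.
#'
#' @param config a [sim_config()].
#' @param truth truth set from [simulate_phased_methylome()] (provides the
#'   imprinted regions).
#' @return data.table with chrom, pos, frequency, depth, sample_id; empty
#'   when `panel_size` is 0.
#' @export
simulate_normal_wgbs_panel <- function(config, truth) {
  empty <- data.table::data.table(
    chrom = character(0), pos = integer(0), frequency = numeric(0),
    depth = integer(0), sample_id = character(0))
  if (config$panel_size == 0L) return(empty)
  world <- .sim_world(config)
  s <- world$sites
  imp <- truth[truth$class == "imprinted", ]
  # map CpGs to imprinted region index (0 = none)
  reg_of <- integer(nrow(s))
  if (nrow(imp)) {
    for (r in seq_len(nrow(imp))) {
      hit <- s$chrom == imp$chrom[r] & s$pos >= imp$start[r] &
        s$pos < imp$end[r]
      reg_of[hit] <- r
    }
  }
  .with_seed(.child_seed(config$seed, "panel"), {
    out <- vector("list", config$panel_size)
    for (k in seq_len(config$panel_size)) {
      freq <- pmin(pmax(s$base + rnorm(nrow(s), 0, 0.02), 0), 1)
      if (nrow(imp)) {
        partial_reg <- runif(nrow(imp)) < config$panel_partial_fraction_at_imprinted
        sel <- reg_of > 0L & partial_reg[pmax(reg_of, 1L)]
        freq[sel] <- runif(sum(sel), 0.40, 0.60)
        # non-partial samples at imprinted loci look fully (un)methylated
        sel0 <- reg_of > 0L & !partial_reg[pmax(reg_of, 1L)]
        freq[sel0] <- ifelse(runif(sum(sel0)) < 0.5,
                             runif(sum(sel0), 0, 0.05),
                             runif(sum(sel0), 0.95, 1))
      }
      deep <- runif(nrow(s)) < config$panel_depth_ge5_fraction
      depth <- ifelse(deep, 5L + rpois(nrow(s), 25),rpois(nrow(s), 2))
      out[[k]] <- data.table::data.table(
        chrom = s$chrom, pos = s$pos, frequency = freq,
        depth = as.integer(depth), sample_id = sprintf("panel%03d", k))
    }
    data.table::rbindlist(out)[]
  })
}

#' Simulate phased allelic RNA counts and TPM per gene
#'
#' Genes are laid out on the simulated chromosomes with 1-10 phased SNPs
#' each. Null genes draw haplotype-1 reads Binomial(n, 0.5) per SNP; planted
#' ASE genes use Binomial(n, ase_maf) on a designated major haplotype. TPM
#' straddles the 1 TPM threshold: planted ASE genes are always expressed
#' (>= 1 TPM), 15% of null genes fall below it, and two high-MAF distractor
#' genes sit below 1 TPM (they must end up not_testable, not ASE). For ASE
#' genes a promoter hypermethylated haplotype is also drawn: the minor
#' expressed haplotype with probability `ase_trans_fraction` (silencing in
#' trans), the major one otherwise.
#'
#' @param config a [sim_config()].
#' @return list(snv_counts, tpm, truth) where truth has gene_id, true_maf,
#'   major_haplotype, hyper_hap for the planted ASE genes.
#' @export
simulate_allelic_expression <- function(config) {
  .with_seed(.child_seed(config$seed, "ase"), {
    n_g <- config$n_genes
    gene_ids <- sprintf("gene%04d", seq_len(n_g))
    is_ase <- rep(FALSE, n_g)
    if (config$n_ase_genes > 0L && config$ase_maf > 0.5)
      is_ase[sample.int(n_g, config$n_ase_genes)] <- TRUE
    n_distract <- min(2L, n_g - sum(is_ase))
    distract <- sample(which(!is_ase), n_distract)

    chrom <- sprintf("chr%d", 1L + (seq_len(n_g) - 1L) %% config$n_chromosomes)
    major <- sample(c("1", "2"), n_g, replace = TRUE)
    tpm <- exp(rnorm(n_g, log(20), 1.2))
    low <- !is_ase & runif(n_g) < 0.15
    tpm[low] <- runif(sum(low), 0.01, 0.99)
    tpm[is_ase] <- pmax(tpm[is_ase], 1.5)
    tpm[distract] <- runif(n_distract, 0.01, 0.99)

    rows <- vector("list", n_g)
    for (g in seq_len(n_g)) {
      n_snp <- sample.int(10L, 1L)
      total <- rpois(1L, config$reads_per_ase_gene)
      per <- as.vector(stats::rmultinom(1L, total, rep(1 / n_snp, n_snp)))
      p_major <- if (is_ase[g] || g %in% distract) config$ase_maf else 0.5
      maj_reads <- rbinom(n_snp, per, p_major)
      h1 <- if (major[g] == "1") maj_reads else per - maj_reads
      rows[[g]] <- data.table::data.table(
        gene_id = gene_ids[g], chrom = chrom[g],
        pos = sort(sample.int(config$chrom_length_bp, n_snp)),
        hap1_reads = h1, hap2_reads = per - h1)
    }
    snv <- data.table::rbindlist(rows)
    snv <- snv[snv$hap1_reads + snv$hap2_reads >= 1L]

    trans <- runif(n_g) < config$ase_trans_fraction
    other <- ifelse(major == "1", "2", "1")
    truth <- data.table::data.table(
      gene_id = gene_ids[is_ase],
      true_maf = config$ase_maf,
      major_haplotype = major[is_ase],
      hyper_hap = ifelse(trans[is_ase], other[is_ase], major[is_ase]))
    list(snv_counts = snv[],
         tpm = data.table::data.table(gene_id = gene_ids, tpm = tpm),
         truth = truth[])
  })
}

#' Simulate allele-specific copy-number segments
#'
#' Tiles each chromosome without gaps or overlap. Exactly
#' `loh_fraction_of_genome` of each chromosome's length is one LOH segment
#' (minor_cn = 0) at a random interior position; the flanks are split into
#' 1-3 heterozygous segments each, mixing balanced (1,1) and imbalanced
#' states.
#'
#' @param config a [sim_config()].
#' @return data.table with chrom, start, end, major_cn, minor_cn.
#' @export
simulate_cn_segments <- function(config) {
  .with_seed(.child_seed(config$seed, "cn"), {
    out <- list()
    L <- config$chrom_length_bp
    for (ci in seq_len(config$n_chromosomes)) {
      ch <- sprintf("chr%d", ci)
      loh_len <- round(config$loh_fraction_of_genome * L)
      segs <- data.table::data.table(
        start = integer(0), end = integer(0),
        major_cn = integer(0), minor_cn = integer(0))
      chop <- function(a, b) {  # split [a,b) into 1-3 het segments
        if (b <= a) return(NULL)
        k <- sample.int(3L, 1L)
        cuts <- sort(unique(c(a, b, a + sample.int(b - a, min(k - 1L, b - a - 1L)))))
        data.table::data.table(
          start = head(cuts, -1L), end = cuts[-1L],
          major_cn = sample(c(1L, 2L, 3L), length(cuts) - 1L, replace = TRUE,
                            prob = c(0.6, 0.3, 0.1)),
          minor_cn = 1L)
      }
      if (loh_len >= L) {
        segs <- data.table::data.table(start = 0L, end = L,
                                       major_cn = 2L, minor_cn = 0L)
      } else if (loh_len > 0) {
        a <- sample.int(L - loh_len, 1L)
        segs <- rbind(chop(0L, a),
                      data.table::data.table(start = a, end = a + loh_len,
                                             major_cn = sample(1:2, 1L),
                                             minor_cn = 0L),
                      chop(a + loh_len, L))
      } else {
        segs <- chop(0L, L)
      }
      segs[, "chrom" := ch]
      out[[ci]] <- segs
    }
    res <- data.table::rbindlist(out)
    data.table::setcolorder(res, c("chrom", "start", "end",
                                   "major_cn", "minor_cn"))
    data.table::setorder(res, chrom, start)
    res[]
  })
}

# random DNA helper
.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate deletions with flanking sequence and planted microhomology
#'
#' A fraction `mh_deletion_fraction_true` of deletions is constructed with a
#' planted 1-5 bp microhomology between the deleted sequence and the right
#' flank; those deletions are forced longer than 3 bp so they count for the
#' microhomology deletion fraction. The remaining deletions (lengths 1-60 bp)
#' are built homology-free by forcing a mismatch at both breakpoint-adjacent
#' bases.
#'
#' @param config a [sim_config()].
#' @return data.table with id, chrom, start, end, deleted_seq, left_flank,
#'   right_flank, planted_mh_len.
#' @export
simulate_deletions_with_flanks <- function(config) {
  .with_seed(.child_seed(config$seed, "deletions"), {
    n <- config$n_deletions
    rows <- vector("list", n)
    bases <- c("A", "C", "G", "T")
    other <- function(b) sample(setdiff(bases, b), 1L)
    for (i in seq_len(n)) {
      planted <- runif(1) < config$mh_deletion_fraction_true
      len <- if (planted) sample(4:60, 1L) else sample(1:60, 1L)
      del <- strsplit(.rand_dna(len), "")[[1]]
      lf <- strsplit(.rand_dna(12L), "")[[1]]
      rf <- strsplit(.rand_dna(12L), "")[[1]]
      # kill accidental homology at both breakpoints
      lf[12] <- other(del[len])
      rf[1] <- other(del[1])
      mh <- 0L
      if (planted) {
        mh <- sample.int(min(5L, len - 1L), 1L)
        rf[seq_len(mh)] <- del[seq_len(mh)]
        if (len > mh) rf[mh + 1L] <- other(del[mh + 1L])
      }
      start <- sample.int(config$chrom_length_bp - len, 1L)
      rows[[i]] <- data.table::data.table(
        id = sprintf("del%04d", i),
        chrom = sprintf("chr%d", 1L + (i - 1L) %% config$n_chromosomes),
        start = start, end = start + len,
        deleted_seq = paste(del, collapse = ""),
        left_flank = paste(lf, collapse = ""),
        right_flank = paste(rf, collapse = ""),
        planted_mh_len = mh)
    }
    data.table::rbindlist(rows)[]
  })
}

#' Write a full synthetic fixture bundle to a directory
#'
#' Emits tumor/normal strand-level call tables, the normal panel, truth set,
#' CN segments, deletions, allelic RNA counts, TPM, a transcript table for
#' the simulated genes, and a manifest. All files are plain TSV/BED with
#' 0-based half-open coordinates.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing).
#' @return Invisibly, a named list of written paths.
#' @export
write_sim_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tum <- simulate_phased_methylome(config, "tumor")
  nor <- simulate_phased_methylome(config, "normal")
  panel <- simulate_normal_wgbs_panel(config, tum$truth)
  cn <- simulate_cn_segments(config)
  dels <- simulate_deletions_with_flanks(config)
  ase <- simulate_allelic_expression(config)

  p <- function(f) file.path(dir, f)
  write_cpg_calls(tum$calls, p("tumor_calls.tsv"))
  write_cpg_calls(nor$calls, p("normal_calls.tsv"))
  data.table::fwrite(panel, p("panel_frequencies.tsv"), sep = "\t")
  data.table::fwrite(tum$truth, p("truth_regions.tsv"), sep = "\t")
  data.table::fwrite(cn, p("cn_segments.bed"), sep = "\t")
  data.table::fwrite(dels, p("deletions.tsv"), sep = "\t")
  data.table::fwrite(ase$snv_counts, p("allelic_counts.tsv"), sep = "\t")
  data.table::fwrite(ase$tpm, p("tpm.tsv"), sep = "\t")
  data.table::fwrite(ase$truth, p("ase_truth.tsv"), sep = "\t")
  manifest <- data.table::data.table(
    file = c("tumor_calls.tsv", "normal_calls.tsv", "panel_frequencies.tsv",
             "truth_regions.tsv", "cn_segments.bed", "deletions.tsv",
             "allelic_counts.tsv", "tpm.tsv", "ase_truth.tsv"),
    coordinates = "0-based half-open")
  data.table::fwrite(manifest, p("MANIFEST.tsv"), sep = "\t")
  invisible(setNames(as.list(p(manifest$file)), manifest$file))
}
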