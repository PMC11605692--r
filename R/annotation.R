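# Strand-aware promoter construction, reciprocal-overlap annotation,
# promoter recurrence across samples, and region-level methylation averages.

#' Build promoter intervals from transcript models
#'
#' Promoters span 1500 bp upstream to 500 bp downstream of the TSS,
#' strand-aware: '+' gives [tss - 1500, tss + 500), '-' gives
#' [tss - 500, tss + 1500); clipped at 0.
#'
#' @param transcripts table with gene_id, transcript_id, chrom, strand, tss.
#' @param upstream,downstream distances in bp.
#' @return data.table: chrom, start, end, gene_id, transcript_id, strand.
#' @export
build_promoters <- function(transcripts, upstream = 1500L,
                            downstream = 500L) {
  tr <- data.table::as.data.table(transcripts)
  .assert(all(tr$strand %in% c("+", "-")), "strand must be '+' or '-'")
  start <- ifelse(tr$strand == "+", tr$tss - upstream, tr$tss - downstream)
  end <- ifelse(tr$strand == "+", tr$tss + downstream, tr$tss + upstream)
  data.table::data.table(
    chrom = tr$chrom, start = pmax(0L, as.integer(start)),
    end = as.integer(end), gene_id = tr$gene_id,
    transcript_id = tr$transcript_id, strand = tr$strand)[]
}

#' Build polyA-site flank intervals
#'
#' [site - 500, site + 500) around each polyA site, clipped at 0; overlapping
#' flanks are not merged.
#'
#' @param polya_sites table with chrom, pos.
#' @param flank_bp half-width in bp.
#' @return data.table: chrom, start, end.
#' @export
build_polya_flanks <- function(polya_sites, flank_bp = 500L) {
  ps <- data.table::as.data.table(polya_sites)
  data.table::data.table(
    chrom = ps$chrom,
    start = pmax(0L, as.integer(ps$pos - flank_bp)),
    end = as.integer(ps$pos + flank_bp))[]
}

#' Reciprocal-50% interval intersection (either-side semantics)
#'
#' Reports a pair (x, y) when the overlap covers at least `fraction` of x OR
#' at least `fraction` of y, matching `bedtools intersect -e -f 0.5 -F 0.5`.
#' Zero-length intervals are rejected (fraction-of-length undefined).
#'
#' @param a,b interval tables (chrom, start, end; 0-based half-open).
#' @param fraction required overlap fraction of either interval.
#' @return data.table of pairs: a_idx, b_idx, overlap_bp.
#' @export
intersect_reciprocal50 <- function(a, b, fraction = 0.5) {
  a <- data.table::as.data.table(a); b <- data.table::as.data.table(b)
  empty <- data.table::data.table(a_idx = integer(0), b_idx = integer(0),
                                  overlap_bp = integer(0))
  if (!nrow(a) || !nrow(b)) return(empty)
  ga <- .as_granges(a); gb <- .as_granges(b)
  ov <- .find_overlaps(ga, gb, minoverlap = 1L)
  if (!length(ov)) return(empty)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(ga)[qi],
                                          IRanges::ranges(gb)[si]))
  la <- a$end[qi] - a$start[qi]; lb <- b$end[si] - b$start[si]
  keep <- w >= fraction * la | w >= fraction * lb
  data.table::data.table(a_idx = qi[keep], b_idx = si[keep],
                         overlap_bp = w[keep])[]
}

#' Annotate aDMRs against genomic feature tracks
#'
#' Each aDMR is tested against every feature set under the reciprocal-50
#' either-side rule and may carry multiple categories. The summary reports
#' the fraction of aDMRs carrying at least one regulatory category.
#'
#' @param admrs aDMR table.
#' @param feature_sets named list of interval tables, e.g.
#'   list(CGI = ..., promoter = ..., enhancer = ..., TF_site = ...,
#'   polyA_flank = ...).
#' @param regulatory categories counted in the summary fraction.
#' @return list(annotations = long table (admr_id, category, feature_idx),
#'   categories = per-aDMR category list (comma-joined, 'none' if empty),
#'   regulatory_fraction = scalar).
#' @export
annotate_admrs <- function(admrs,
                           feature_sets,
                           regulatory = c("CGI", "TF_site", "promoter",
                                          "enhancer", "polyA_flank")) {
  admrs <- .with_admr_id(admrs)
  ann <- list()
  for (cat in names(feature_sets)) {
    fs <- data.table::as.data.table(feature_sets[[cat]])
    if (!nrow(fs)) next
    pairs <- intersect_reciprocal50(admrs, fs)
    if (nrow(pairs))
      ann[[cat]] <- data.table::data.table(
        admr_id = admrs$admr_id[pairs$a_idx], category = cat,
        feature_idx = pairs$b_idx)
  }
  annotations <- if (length(ann)) data.table::rbindlist(ann) else
    data.table::data.table(admr_id = character(0), category = character(0),
                           feature_idx = integer(0))
  cats <- vapply(admrs$admr_id, function(id) {
    got <- unique(annotations$category[annotations$admr_id == id])
    if (length(got)) paste(sort(got), collapse = ",") else "none"
  }, character(1))
  has_reg <- vapply(admrs$admr_id, function(id)
    any(annotations$category[annotations$admr_id == id] %in% regulatory),
    logical(1))
  list(annotations = annotations[],
       categories = data.table::data.table(admr_id = admrs$admr_id,
                                           categories = cats),
       regulatory_fraction = if (nrow(admrs)) mean(has_reg) else NaN)
}

#' Transcripts with recurrent promoter aDMRs across samples
#'
#' Counts, per transcript, the distinct samples whose tumor-specific aDMRs
#' hit its promoter under the reciprocal-50 rule; a transcript (and its gene)
#' is recurrent when hit in at least `min_samples` samples.
#'
#' @param per_sample_admrs named list of per-sample aDMR tables.
#' @param promoters promoter table from [build_promoters()].
#' @param min_samples recurrence threshold (distinct samples).
#' @return data.table: gene_id, transcript_id, n_samples, recurrent.
#' @export
recurrent_promoter_admrs <- function(per_sample_admrs, promoters,
                                     min_samples = 2L) {
  promoters <- data.table::as.data.table(promoters)
  hits <- list()
  for (s in names(per_sample_admrs)) {
    adm <- data.table::as.data.table(per_sample_admrs[[s]])
    if (!nrow(adm)) next
    pairs <- intersect_reciprocal50(adm, promoters)
    if (nrow(pairs))
      hits[[s]] <- data.table::data.table(
        sample = s,
        transcript_id = promoters$transcript_id[pairs$b_idx],
        gene_id = promoters$gene_id[pairs$b_idx])
  }
  base <- data.table::data.table(gene_id = promoters$gene_id,
                                 transcript_id = promoters$transcript_id)
  base <- unique(base)
  if (!length(hits)) {
    base[, "n_samples" := 0L]
  } else {
    h <- unique(data.table::rbindlist(hits))
    sample <- transcript_id <- gene_id <- NULL
    cnt <- h[, list(n_samples = length(unique(sample))),
             by = list(gene_id, transcript_id)]
    base <- merge(base, cnt, by = c("gene_id", "transcript_id"),
                  all.x = TRUE)
    base$n_samples[is.na(base$n_samples)] <- 0L
  }
  base[, "recurrent" := base$n_samples >= min_samples]
  data.table::setorder(base, -n_samples, gene_id)
  base[]
}

#' Average methylation over a region, with threshold classification
#'
#' Unweighted mean frequency over CpGs inside the region (depth-weighted
#' behind `weighted = TRUE`). Classified methylated when the mean STRICTLY
#' exceeds `threshold` (default 0.25). Regions containing no CpG return NaN
#' and classification NA.
#'
#' @param regions interval table (chrom, start, end).
#' @param frequencies methylation records (chrom, pos, frequency, optional
#'   depth).
#' @param threshold classification cutoff.
#' @param weighted depth-weighted mean instead of unweighted.
#' @return regions with columns mean_methylation, n_cpgs, methylated.
#' @export
average_region_methylation <- function(regions, frequencies,
                                       threshold = 0.25, weighted = FALSE) {
  regions <- data.table::as.data.table(regions)
  frequencies <- data.table::as.data.table(frequencies)
  out <- data.table::copy(regions)
  mm <- rep(NaN, nrow(regions)); nc <- integer(nrow(regions))
  if (nrow(regions) && nrow(frequencies)) {
    gr_cpg <- GenomicRanges::GRanges(
      frequencies$chrom, IRanges::IRanges(frequencies$pos + 1L,
                                          frequencies$pos + 1L))
    ov <- .find_overlaps(gr_cpg, .as_granges(regions))
    if (length(ov)) {
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      for (r in unique(sh)) {
        i <- qh[sh == r]
        nc[r] <- length(i)
        mm[r] <- if (weighted && "depth" %in% names(frequencies))
          stats::weighted.mean(frequencies$frequency[i],
                               frequencies$depth[i])
        else mean(frequencies$frequency[i])
      }
    }
  }
  out[, "mean_methylation" := mm]
  out[, "n_cpgs" := nc]
  out[, "methylated" := ifelse(nc > 0L, mm > threshold, NA)]
  out[]
}

#' Read a BED3+ file as an interval table
#'
#' @param path BED file (no header, at least chrom/start/end).
#' @return data.table with chrom, start, end (extra columns kept as V4...).
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  data.table::setnames(dt, 1:3, c("chrom", "start", "end"))
  .assert(all(dt$end > dt$start), "BED has zero/negative-length interval")
  dt[]
}
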