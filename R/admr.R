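# Allelic DMR detection between haplotype 1 and haplotype 2 of one sample.
#
# The approach mirrors smoothing-based two-group dispersion-aware DMR
# callers: per-CpG haplotype frequencies are smoothed by a coverage-weighted
# window mean, a Wald statistic with beta-binomial variance is computed per
# CpG, and runs of significant CpGs are segmented into regions, which are
# finally filtered on the raw (unsmoothed) allelic methylation difference.

#' aDMR caller parameters
#'
#' Defaults mirror the segmentation defaults of standard DMR callers:
#' per-CpG p-value threshold 1e-5, at least 3 CpGs and 50 bp per region,
#' runs merged across gaps of up to 100 bp, at least half the CpGs in a
#' region significant, smoothing window 500 bp, and a minimum absolute
#' allelic difference of 0.15 applied last.
#'
#' @param p_threshold per-CpG significance threshold.
#' @param min_cpgs minimum CpGs per region.
#' @param min_len minimum region length in bp.
#' @param merge_bp merge significant runs separated by at most this many bp.
#' @param pct_sig minimum fraction of significant CpGs within a region.
#' @param delta_min minimum |mean_meth_h1 - mean_meth_h2|.
#' @param window_bp smoothing window width (full width, centred).
#' @return list of class `admr_params`.
#' @export
admr_params <- function(p_threshold = 1e-5, min_cpgs = 3L, min_len = 50L,
                        merge_bp = 100L, pct_sig = 0.5, delta_min = 0.15,
                        window_bp = 500L) {
  structure(as.list(environment()), class = "admr_params")
}

# Wide per-site haplotype table from strand-merged calls. Sites must carry
# both haplotypes with coverage; others are returned flagged in `skipped`.
.hap_wide <- function(calls) {
  calls <- data.table::as.data.table(calls)
  ph <- calls[calls$haplotype %in% c("1", "2") & calls$n_total > 0L]
  dup <- duplicated(ph[, c("chrom", "pos", "haplotype")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate position within a haplotype at %s:%d",
                 ph$chrom[i], ph$pos[i]), call. = FALSE)
  }
  wide <- data.table::dcast(
    ph, chrom + pos ~ haplotype,
    value.var = c("n_methylated", "n_total"), fill = NA)
  for (col in c("n_methylated_1", "n_methylated_2", "n_total_1", "n_total_2"))
    if (!col %in% names(wide)) wide[, (col) := NA_integer_]
  ok <- !is.na(wide$n_total_1) & !is.na(wide$n_total_2)
  data.table::setorder(wide, chrom, pos)
  list(sites = wide[ok], skipped = wide[!ok, c("chrom", "pos")])
}

# Windowed coverage-weighted smoothing for one sorted position vector.
# Returns smoothed frequency plus window totals needed for the variance.
.smooth_one <- function(pos, m, n, window_bp) {
  half <- window_bp / 2
  lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
  hi <- findInterval(pos + half, pos)
  cm <- cumsum(as.numeric(m)); cn <- cumsum(as.numeric(n))
  cs <- cumsum(as.numeric(n) * (as.numeric(n) - 1))
  at <- function(cum, i) ifelse(i >= 1L, cum[pmax(i, 1L)], 0)
  Mw <- at(cm, hi) - at(cm, lo - 1L)
  Nw <- at(cn, hi) - at(cn, lo - 1L)
  Sw <- at(cs, hi) - at(cs, lo - 1L)
  list(p_smooth = ifelse(Nw > 0, Mw / Nw, NA_real_), N_w = Nw, S_w = Sw)
}

#' Smooth per-haplotype methylation frequencies
#'
#' Coverage-weighted mean of raw per-CpG frequencies over all CpGs within
#' +/- window_bp/2 of each site, per haplotype. A site isolated in its
#' window returns its raw frequency. Only sites covered on both haplotypes
#' are smoothed; single-haplotype sites are reported in attribute `skipped`.
#'
#' @param calls strand-merged call table.
#' @param window_bp full smoothing window width in bp.
#' @return data.table with per-site raw and smoothed frequencies and window
#'   coverage totals per haplotype.
#' @export
smooth_haplotype_frequencies <- function(calls, window_bp = 500L) {
  hw <- .hap_wide(calls)
  s <- hw$sites
  out <- s[, {
    s1 <- .smooth_one(pos, n_methylated_1, n_total_1, window_bp)
    s2 <- .smooth_one(pos, n_methylated_2, n_total_2, window_bp)
    list(pos = pos,
         n1 = n_total_1, n2 = n_total_2,
         p1_raw = n_methylated_1 / n_total_1,
         p2_raw = n_methylated_2 / n_total_2,
         p1_smooth = s1$p_smooth, p2_smooth = s2$p_smooth,
         N1_w = s1$N_w, N2_w = s2$N_w, S1_w = s1$S_w, S2_w = s2$S_w)
  }, by = "chrom"]
  data.table::setattr(out, "skipped", hw$skipped)
  out[]
}

# Method-of-moments beta-binomial dispersion pooled over a chromosome,
# estimated from cross-haplotype differences: under the allelic null both
# haplotypes share the site frequency, so between-site heterogeneity cancels
# in p1 - p2 and E[(p1-p2)^2] = p(1-p)[(1+(n1-1)rho)/n1 + (1+(n2-1)rho)/n2].
# Solved per site and averaged after dropping the top decile of squared
# differences (true allelic signal would otherwise inflate rho); floored
# at 0.
# Sites carrying true allelic signal are excluded as outliers before
# pooling: under the null d2 / a is approximately chi-square(1), so sites
# beyond its 99.9% quantile are treated as signal, then rho solves the
# aggregate moment equation sum(d2) = sum(a) + rho * sum(b).
.pool_dispersion <- function(sm) {
  n1 <- sm$n1; n2 <- sm$n2
  pi0 <- (sm$p1_raw * n1 + sm$p2_raw * n2) / (n1 + n2)
  d2 <- (sm$p1_raw - sm$p2_raw)^2
  v <- pi0 * (1 - pi0)
  a <- v * (1 / n1 + 1 / n2)
  b <- v * ((n1 - 1) / n1 + (n2 - 1) / n2)
  keep <- n1 >= 2 & n2 >= 2 & pi0 > 0.01 & pi0 < 0.99 &
    d2 <= stats::qchisq(0.999, 1) * a
  if (!any(keep)) return(0)
  max(0, sum(d2[keep] - a[keep]) / sum(b[keep]))
}

#' Per-CpG Wald test of allelic methylation difference
#'
#' Tests p1_smooth - p2_smooth against zero with a beta-binomial variance
#' v = p(1-p) (N_w + rho * sum n_i(n_i - 1)) / N_w^2 per haplotype, where the
#' sums run over the smoothing window (for an isolated site this reduces to
#' p(1-p)(1 + (n-1) rho) / n). For the variance, p is shrunk towards 0.5 by
#' half a pseudo-read so degenerate all-0/all-1 windows keep a finite
#' statistic; a site with identical smoothed frequencies gets p = 1. The
#' dispersion rho is pooled per chromosome by method of moments (floored at
#' 0) unless supplied.
#'
#' @param calls strand-merged call table.
#' @param window_bp smoothing window (bp).
#' @param rho beta-binomial dispersion; NULL to estimate per chromosome.
#' @return data.table of per-CpG results: raw/smoothed frequencies,
#'   `wald_stat`, `p_value`, plus the pooled `rho` used. Attribute `skipped`
#'   lists single-haplotype sites.
#' @export
test_per_cpg <- function(calls, window_bp = 500L, rho = NULL) {
  sm <- smooth_haplotype_frequencies(calls, window_bp)
  skipped <- attr(sm, "skipped")
  p_value <- wald_stat <- NULL
  out <- sm[, {
    r <- if (is.null(rho)) .pool_dispersion(.SD) else rho
    shrink <- function(p, N) (p * N + 0.5) / (N + 1)
    v_of <- function(p, Nw, Sw) {
      ps <- shrink(p, Nw)
      ps * (1 - ps) * (Nw + r * Sw) / Nw^2
    }
    v <- v_of(p1_smooth, N1_w, S1_w) + v_of(p2_smooth, N2_w, S2_w)
    w <- (p1_smooth - p2_smooth) / sqrt(v)
    w[p1_smooth == p2_smooth] <- 0
    c(.SD, list(wald_stat = w, p_value = pmin(1, 2 * pnorm(-abs(w))),
                rho = r))
  }, by = "chrom"]
  data.table::setattr(out, "skipped", skipped)
  out[]
}

#' Segment per-CpG test results into aDMRs
#'
#' Candidate regions are maximal runs of consecutive CpGs with
#' p < p_threshold; runs separated by at most merge_bp are merged. A region
#' spans from its first to its last significant CpG and includes every CpG
#' in between. Regions are kept when they have at least min_cpgs CpGs, span
#' at least min_len bp, and at least pct_sig of their CpGs are significant;
#' the allelic difference is the unweighted mean of RAW haplotype
#' frequencies over the region's CpGs, and |diff_methyl| >= delta_min is
#' applied last.
#'
#' @param results output of [test_per_cpg()].
#' @param params an [admr_params()].
#' @return data.table of aDMRs: chrom, start, end (0-based half-open),
#'   n_cpgs, mean_meth_h1, mean_meth_h2, diff_methyl, area_stat, min_p.
#' @export
call_admrs <- function(results, params = admr_params()) {
  results <- data.table::as.data.table(results)
  data.table::setorder(results, chrom, pos)
  empty <- data.table::data.table(
    chrom = character(0), start = integer(0), end = integer(0),
    n_cpgs = integer(0), mean_meth_h1 = numeric(0), mean_meth_h2 = numeric(0),
    diff_methyl = numeric(0), area_stat = numeric(0), min_p = numeric(0))
  out <- list()
  for (ch in unique(results$chrom)) {
    d <- results[results$chrom == ch]
    sig <- which(d$p_value < params$p_threshold)
    if (!length(sig)) next
    # maximal runs of consecutive significant site indices
    brk <- c(0L, which(diff(sig) > 1L), length(sig))
    runs <- lapply(seq_len(length(brk) - 1L), function(i)
      sig[(brk[i] + 1L):brk[i + 1L]])
    # merge runs whose genomic gap is <= merge_bp
    merged <- list(runs[[1]])
    for (r in runs[-1]) {
      last <- merged[[length(merged)]]
      gap <- d$pos[r[1]] - (d$pos[last[length(last)]] + 2L)
      if (gap <= params$merge_bp) {
        merged[[length(merged)]] <- c(last, r)
      } else merged <- c(merged, list(r))
    }
    for (r in merged) {
      i1 <- r[1]; i2 <- r[length(r)]
      span <- i1:i2
      n_cpgs <- length(span)
      len <- d$pos[i2] + 2L - d$pos[i1]
      frac_sig <- length(r) / n_cpgs
      if (n_cpgs < params$min_cpgs || len < params$min_len ||
          frac_sig < params$pct_sig) next
      m1 <- mean(d$p1_raw[span]); m2 <- mean(d$p2_raw[span])
      if (abs(m1 - m2) < params$delta_min) next
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = ch, start = d$pos[i1], end = d$pos[i2] + 2L,
        n_cpgs = n_cpgs, mean_meth_h1 = m1, mean_meth_h2 = m2,
        diff_methyl = m1 - m2,
        area_stat = sum(d$wald_stat[span]), min_p = min(d$p_value[span]))
    }
  }
  if (!length(out)) return(empty)
  res <- data.table::rbindlist(out)
  data.table::setorder(res, chrom, start)
  res[]
}

#' Classify the copy-number context of aDMRs
#'
#' The segment covering each aDMR midpoint decides: minor_cn = 0 is LOH,
#' major = minor = 1 is HetDip, any other heterozygous state is HetCNV, and
#' no covering segment is unknown.
#'
#' @param admrs aDMR table (chrom, start, end).
#' @param segments CN segment table (chrom, start, end, major_cn, minor_cn).
#' @return the aDMR table with a `cn_context` column added.
#' @export
classify_cn_context <- function(admrs, segments) {
  admrs <- data.table::as.data.table(admrs)
  segments <- data.table::as.data.table(segments)
  ctx <- rep("unknown", nrow(admrs))
  if (nrow(admrs) && nrow(segments)) {
    mid <- (admrs$start + admrs$end) %/% 2L
    gr_mid <- GenomicRanges::GRanges(admrs$chrom,
                                     IRanges::IRanges(mid + 1L, mid + 1L))
    gr_seg <- .as_granges(segments)
    ov <- .find_overlaps(gr_mid, gr_seg, select = "first")
    hit <- !is.na(ov)
    maj <- segments$major_cn[ov[hit]]; mnr <- segments$minor_cn[ov[hit]]
    ctx[hit] <- ifelse(mnr == 0L, "LOH",
                       ifelse(maj == 1L & mnr == 1L, "HetDip", "HetCNV"))
  }
  out <- data.table::copy(admrs)
  out[, "cn_context" := ctx]
  out[]
}

#' Write aDMRs as BED6+
#'
#' Columns: chrom, start, end, name, score = round(1000 |diff_methyl|),
#' strand '.', then n_cpgs, mean_meth_h1, mean_meth_h2, diff_methyl, min_p,
#' cn_context.
#'
#' @param admrs aDMR table.
#' @param path output path.
#' @export
write_admr_bed <- function(admrs, path) {
  admrs <- data.table::as.data.table(admrs)
  out <- data.table::data.table(
    chrom = admrs$chrom, start = admrs$start, end = admrs$end,
    name = sprintf("aDMR_%05d", seq_len(nrow(admrs))),
    score = round(1000 * abs(admrs$diff_methyl)), strand = ".",
    n_cpgs = admrs$n_cpgs, mean_meth_h1 = admrs$mean_meth_h1,
    mean_meth_h2 = admrs$mean_meth_h2, diff_methyl = admrs$diff_methyl,
    min_p = admrs$min_p,
    cn_context = if ("cn_context" %in% names(admrs)) admrs$cn_context
                 else "unknown")
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
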