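# Genomic-scar features (LOH / TAI / LST), microhomology deletion fraction,
# HRDetect logistic scoring, and HR-gene promoter methylation calls.

# Published HRDetect logistic model: intercept and the coefficients for
# (SBS3, SBS8, SV3, SV5, HRD index, microhomology deletion fraction).
.HRDETECT_INTERCEPT <- -3.364
.HRDETECT_COEFS <- c(sbs3 = 1.611, sbs8 = 0.091, sv3 = 1.153,
                     sv5 = 0.847, hrd_index = 0.667, mh_del_fraction = 2.398)

#' Microhomology length of a deletion
#'
#' Longest k such that the first k bases of the deleted sequence equal the
#' first k bases of the right flank, or the last k bases of the deleted
#' sequence equal the last k bases of the left flank; the larger of the two,
#' capped at the deletion length.
#'
#' @param deleted_seq,left_flank,right_flank nucleotide strings (vectorized).
#' @return integer vector of microhomology lengths.
#' @export
microhomology_length <- function(deleted_seq, left_flank, right_flank) {
  one <- function(del, lf, rf) {
    L <- nchar(del)
    if (L == 0L) return(0L)
    d <- strsplit(del, "")[[1]]
    r <- strsplit(rf, "")[[1]]
    l <- strsplit(lf, "")[[1]]
    kr <- 0L
    for (k in seq_len(min(L, length(r)))) {
      if (d[k] == r[k]) kr <- k else break
    }
    kl <- 0L
    nl <- length(l)
    for (k in seq_len(min(L, nl))) {
      if (d[L - k + 1L] == l[nl - k + 1L]) kl <- k else break
    }
    min(max(kr, kl), L)
  }
  mapply(one, deleted_seq, left_flank, right_flank, USE.NAMES = FALSE)
}

#' Microhomology deletion fraction
#'
#' Numerator: deletions longer than 3 bp with microhomology length at least
#' `mh_min`. Denominator: all deletions by default; deletions > 3 bp when
#' `denominator = "gt3bp"`. With no deletion longer than 3 bp the fraction is
#' undefined and returned as 0 with a warning.
#'
#' @param deletions table with deleted_seq, left_flank, right_flank (and
#'   implicitly length = nchar(deleted_seq)).
#' @param mh_min minimum microhomology length to count.
#' @param denominator "all" or "gt3bp".
#' @return fraction in [0, 1].
#' @export
microhomology_deletion_fraction <- function(deletions, mh_min = 1L,
                                            denominator = c("all", "gt3bp")) {
  denominator <- match.arg(denominator)
  deletions <- data.table::as.data.table(deletions)
  if (!nrow(deletions)) {
    warning("no deletions; microhomology fraction set to 0")
    return(0)
  }
  len <- nchar(deletions$deleted_seq)
  if (!any(len > 3L)) {
    warning("no deletion longer than 3 bp; microhomology fraction set to 0")
    return(0)
  }
  mh <- microhomology_length(deletions$deleted_seq, deletions$left_flank,
                             deletions$right_flank)
  num <- sum(len > 3L & mh >= mh_min)
  den <- if (denominator == "all") length(len) else sum(len > 3L)
  num / den
}

# Merge adjacent segments with identical (major, minor) state per chromosome.
.merge_equal_states <- function(segs) {
  segs <- data.table::as.data.table(segs)
  data.table::setorder(segs, chrom, start)
  out <- list()
  for (ch in unique(segs$chrom)) {
    d <- segs[segs$chrom == ch]
    keep <- c(TRUE, d$major_cn[-1] != d$major_cn[-nrow(d)] |
                    d$minor_cn[-1] != d$minor_cn[-nrow(d)])
    grp <- cumsum(keep)
    m <- d[, list(chrom = chrom[1], start = min(start), end = max(end),
                  major_cn = major_cn[1], minor_cn = minor_cn[1]),
           by = list(grp = grp)]
    m[, "grp" := NULL]
    out[[ch]] <- m
  }
  data.table::rbindlist(out)
}

# Absorb segments shorter than min_len into their larger neighbor (state of
# the longer adjacent segment wins), then re-merge equal states.
.smooth_small_segments <- function(segs, min_len) {
  segs <- .merge_equal_states(segs)
  out <- list()
  for (ch in unique(segs$chrom)) {
    d <- segs[segs$chrom == ch]
    repeat {
      len <- d$end - d$start
      small <- which(len < min_len)
      if (!length(small) || nrow(d) == 1L) break
      i <- small[1]
      left_len <- if (i > 1L) len[i - 1L] else -1
      right_len <- if (i < nrow(d)) len[i + 1L] else -1
      if (left_len >= right_len) {
        d$end[i - 1L] <- d$end[i]
      } else {
        d$start[i + 1L] <- d$start[i]
      }
      d <- d[-i]
      d <- .merge_equal_states(d)
    }
    out[[ch]] <- d
  }
  data.table::rbindlist(out)
}

#' Genomic scar scores: LOH, TAI and LST
#'
#' LOH: segments with minor_cn = 0 longer than `loh_min_len` (15 Mb) that do
#' not span a whole chromosome. TAI: allelically imbalanced segments
#' (major != minor) that reach a chromosome end without crossing the
#' centromere. LST: breakpoints between adjacent segments both at least
#' `lst_min_len` (10 Mb) long, counted per chromosome arm after absorbing
#' segments shorter than `lst_smooth_len` (3 Mb) into their neighbors.
#' Adjacent equal-state segments are merged before any counting, so the
#' scores are invariant under state-preserving subdivision.
#'
#' @param segments CN table (chrom, start, end, major_cn, minor_cn).
#' @param karyotype per-chromosome table (chrom, length, centromere).
#' @param loh_min_len,lst_min_len,lst_smooth_len thresholds in bp.
#' @return list(loh, tai, lst) of non-negative integer counts.
#' @export
scar_scores <- function(segments, karyotype, loh_min_len = 15e6,
                        lst_min_len = 10e6, lst_smooth_len = 3e6) {
  segs <- .merge_equal_states(segments)
  karyotype <- data.table::as.data.table(karyotype)
  loh <- 0L; tai <- 0L; lst <- 0L
  for (ch in unique(segs$chrom)) {
    d <- segs[segs$chrom == ch]
    data.table::setorder(d, start)
    k <- karyotype[karyotype$chrom == ch]
    .assert(nrow(k) == 1L, "karyotype missing chromosome %s", ch)
    chrom_len <- k$length; cen <- k$centromere

    len <- d$end - d$start
    whole <- d$start <= 0L & d$end >= chrom_len
    loh <- loh + sum(d$minor_cn == 0L & len > loh_min_len & !whole)

    imb <- d$major_cn != d$minor_cn
    at_start <- d$start <= 0L
    at_end <- d$end >= chrom_len
    crosses_cen <- d$start < cen & d$end > cen
    tai <- tai + sum(imb & (at_start | at_end) & !crosses_cen & !whole)

    # LST per arm: split at the centromere, smooth, count big-big breakpoints
    for (arm in list(c(0, cen), c(cen, chrom_len))) {
      a <- d[d$end > arm[1] & d$start < arm[2]]
      if (nrow(a) < 2L) next
      a <- data.table::copy(a)
      a$start <- pmax(a$start, arm[1]); a$end <- pmin(a$end, arm[2])
      a <- .smooth_small_segments(a, lst_smooth_len)
      if (nrow(a) < 2L) next
      alen <- a$end - a$start
      lst <- lst + sum(alen[-nrow(a)] >= lst_min_len &
                         alen[-1] >= lst_min_len)
    }
  }
  list(loh = as.integer(loh), tai = as.integer(tai), lst = as.integer(lst))
}

#' HRD index
#'
#' Arithmetic sum of the LOH, TAI and LST scar scores.
#'
#' @param scores list with loh, tai, lst.
#' @return integer.
#' @export
hrd_index <- function(scores) {
  as.integer(scores$loh + scores$tai + scores$lst)
}

#' Log-transform and z-normalize HRDetect features over a cohort
#'
#' Per feature: x -> ln(x + 1), then centred and scaled to unit standard
#' deviation over the cohort. A zero-variance feature maps to all-zero z with
#' a warning. Supplying `center`/`scale` (named vectors on the ln(x+1)
#' scale) switches to external standardization, e.g. training-cohort moments.
#'
#' @param features data.frame/data.table with columns sbs3, sbs8, sv3, sv5,
#'   hrd_index, mh_del_fraction (rows = samples).
#' @param center,scale optional externally supplied means / SDs.
#' @return matrix of standardized features, same column order.
#' @export
standardize_features <- function(features, center = NULL, scale = NULL) {
  cols <- names(.HRDETECT_COEFS)
  features <- data.table::as.data.table(features)
  .assert(all(cols %in% names(features)),
          "features missing columns: %s",
          paste(setdiff(cols, names(features)), collapse = ", "))
  x <- as.matrix(features[, cols, with = FALSE])
  .assert(all(x >= 0), "HRDetect features must be non-negative")
  lx <- log(x + 1)
  if (is.null(center) != is.null(scale))
    stop("supply both center and scale, or neither", call. = FALSE)
  if (is.null(center)) {
    .assert(nrow(lx) >= 2L, "cohort standardization needs >= 2 samples")
    center <- colMeans(lx)
    scale <- apply(lx, 2, sd)
  } else {
    center <- center[cols]; scale <- scale[cols]
  }
  z <- sweep(lx, 2, center, "-")
  zero <- !is.finite(scale) | scale == 0
  if (any(zero)) {
    warning(sprintf("zero-variance feature(s): %s; z set to 0",
                    paste(cols[zero], collapse = ", ")))
    scale[zero] <- Inf
  }
  sweep(z, 2, scale, "/")
}

#' HRDetect logistic score
#'
#' score = logistic(intercept + sum(coef_i * z_i)) with the published
#' intercept -3.364 and coefficients (1.611, 0.091, 1.153, 0.847, 0.667,
#' 2.398) for standardized (SBS3, SBS8, SV3, SV5, HRD index, microhomology
#' deletion fraction), in that order.
#'
#' @param z matrix or vector of standardized features (columns in the order
#'   sbs3, sbs8, sv3, sv5, hrd_index, mh_del_fraction).
#' @return numeric score(s) in (0, 1).
#' @export
hrdetect_score <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  .assert(ncol(z) == 6L, "expected 6 standardized features")
  eta <- .HRDETECT_INTERCEPT + as.vector(z %*% .HRDETECT_COEFS)
  1 / (1 + exp(-eta))
}

#' Classify HRDetect scores as high
#'
#' High if and only if score >= threshold (default 0.7).
#'
#' @param score numeric score(s).
#' @param threshold decision boundary.
#' @return character vector, "high" or "not_high".
#' @export
classify_hrd_high <- function(score, threshold = 0.7) {
  ifelse(score >= threshold, "high", "not_high")
}

#' HR-gene promoter methylation fraction
#'
#' A promoter CpG is called methylated when its tumor frequency strictly
#' exceeds the normal-tissue mean + 1 SD at that site. The fraction of
#' methylated CpGs over evaluable CpGs is returned per promoter, with LOH
#' status from the CN segment covering the promoter midpoint.
#'
#' @param promoters promoter table (chrom, start, end, gene_id).
#' @param tumor_freqs tumor records (chrom, pos, frequency).
#' @param normal_stats per-site normal moments (chrom, pos, mean, sd).
#' @param segments optional CN segments for LOH status.
#' @param n_sd multiplier on the normal SD.
#' @return data.table: gene_id, n_sites, fraction_methylated_sites,
#'   loh_status.
#' @export
promoter_methylation_fraction <- function(promoters, tumor_freqs,
                                          normal_stats, segments = NULL,
                                          n_sd = 1) {
  promoters <- data.table::as.data.table(promoters)
  tumor_freqs <- data.table::as.data.table(tumor_freqs)
  normal_stats <- data.table::as.data.table(normal_stats)
  merged <- merge(tumor_freqs[, c("chrom", "pos", "frequency")],
                  normal_stats[, c("chrom", "pos", "mean", "sd")],
                  by = c("chrom", "pos"))
  out <- data.table::data.table(
    gene_id = promoters$gene_id,
    n_sites = 0L,
    fraction_methylated_sites = NA_real_)
  if (nrow(merged) && nrow(promoters)) {
    gr_cpg <- GenomicRanges::GRanges(
      merged$chrom, IRanges::IRanges(merged$pos + 1L, merged$pos + 1L))
    ov <- .find_overlaps(gr_cpg, .as_granges(promoters))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    meth <- merged$frequency > merged$mean + n_sd * merged$sd
    for (r in unique(sh)) {
      i <- qh[sh == r]
      out$n_sites[r] <- length(i)
      out$fraction_methylated_sites[r] <- mean(meth[i])
    }
  }
  loh_status <- rep("unknown", nrow(promoters))
  if (!is.null(segments)) {
    ctx <- classify_cn_context(promoters, segments)$cn_context
    loh_status <- ifelse(ctx == "LOH", "LOH",
                         ifelse(ctx == "unknown", "unknown", "HET"))
  }
  out[, "loh_status" := loh_status]
  out[]
}
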