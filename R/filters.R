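# Three-stage exclusion cascade reducing raw tumor aDMRs to tumor-specific
# aDMRs: matched-normal overlap, partial methylation in a normal WGBS panel,
# and proximity to known imprinted regions. Each stage only flags; removal
# happens once at the end, so the flags commute.

# ensure an admr_id column (stable within the table)
.with_admr_id <- function(admrs) {
  admrs <- data.table::as.data.table(admrs)
  if (!"admr_id" %in% names(admrs))
    admrs[, "admr_id" := sprintf("aDMR_%05d", seq_len(nrow(admrs)))]
  admrs
}

#' Flag tumor aDMRs overlapping matched-normal aDMRs
#'
#' Any overlap of at least 1 bp with an aDMR called in the matched normal
#' sample flags the tumor aDMR `matched_normal`. Half-open interval
#' semantics: touching intervals do not overlap.
#'
#' @param tumor_admrs,normal_admrs aDMR tables (chrom, start, end).
#' @return tumor aDMR table with logical column `flag_matched_normal`.
#' @export
exclude_matched_normal <- function(tumor_admrs, normal_admrs) {
  tumor_admrs <- .with_admr_id(tumor_admrs)
  flag <- rep(FALSE, nrow(tumor_admrs))
  if (nrow(tumor_admrs) && nrow(normal_admrs)) {
    ov <- .find_overlaps(.as_granges(tumor_admrs),
                                      .as_granges(normal_admrs),
                                      minoverlap = 1L)
    flag[unique(S4Vectors::queryHits(ov))] <- TRUE
  }
  out <- data.table::copy(tumor_admrs)
  out[, "flag_matched_normal" := flag]
  out[]
}

#' Partial-methylation profile of an aDMR against a normal WGBS panel
#'
#' Per panel sample, CpGs inside the aDMR with depth >= 5 are evaluable; the
#' sample itself is evaluable when it has at least `min_cpgs` (5) such CpGs.
#' A CpG is partially methylated when its frequency lies in [0.35, 0.65]
#' (inclusive); an evaluable sample counts as partial when MORE than
#' `pct_partial` (60%) of its evaluable CpGs are partial (strict).
#'
#' @param admrs aDMR table.
#' @param panel panel records (chrom, pos, frequency, depth, sample_id).
#' @param min_depth,min_cpgs,partial_lo,partial_hi,pct_partial thresholds.
#' @return data.table: admr_id, n_panel_samples_evaluable,
#'   n_panel_samples_partial.
#' @export
partial_methylation_profile <- function(admrs, panel, min_depth = 5L,
                                        min_cpgs = 5L, partial_lo = 0.35,
                                        partial_hi = 0.65,
                                        pct_partial = 0.60) {
  admrs <- .with_admr_id(admrs)
  prof <- data.table::data.table(
    admr_id = admrs$admr_id,
    n_panel_samples_evaluable = 0L,
    n_panel_samples_partial = 0L)
  panel <- data.table::as.data.table(panel)
  if (!nrow(admrs) || !nrow(panel)) return(prof[])
  deep <- panel[panel$depth >= min_depth]
  if (!nrow(deep)) return(prof[])
  gr_cpg <- GenomicRanges::GRanges(deep$chrom,
                                   IRanges::IRanges(deep$pos + 1L,
                                                    deep$pos + 1L))
  ov <- .find_overlaps(gr_cpg, .as_granges(admrs))
  if (!length(ov)) return(prof[])
  hits <- data.table::data.table(
    admr = S4Vectors::subjectHits(ov),
    sample_id = deep$sample_id[S4Vectors::queryHits(ov)],
    partial = deep$frequency[S4Vectors::queryHits(ov)] >= partial_lo &
              deep$frequency[S4Vectors::queryHits(ov)] <= partial_hi)
  partial <- admr <- sample_id <- NULL
  per <- hits[, list(n_cpgs = .N, frac_partial = mean(partial)),
              by = list(admr, sample_id)]
  per <- per[per$n_cpgs >= min_cpgs]
  if (!nrow(per)) return(prof[])
  agg <- per[, list(n_eval = .N,
                    n_part = sum(frac_partial > pct_partial)), by = "admr"]
  prof$n_panel_samples_evaluable[agg$admr] <- agg$n_eval
  prof$n_panel_samples_partial[agg$admr] <- agg$n_part
  prof[]
}

#' Flag aDMRs partially methylated in too much of the panel
#'
#' Flags `panel_partial` when the number of partial panel samples strictly
#' exceeds `max_fraction` (1%) of the panel size. An empty panel flags
#' nothing.
#'
#' @param admrs aDMR table.
#' @param profiles output of [partial_methylation_profile()].
#' @param panel_size total number of panel samples.
#' @param max_fraction strict flagging threshold.
#' @return aDMR table with logical column `flag_panel_partial`.
#' @export
exclude_panel_partial <- function(admrs, profiles, panel_size,
                                  max_fraction = 0.01) {
  admrs <- .with_admr_id(admrs)
  profiles <- data.table::as.data.table(profiles)
  np <- profiles$n_panel_samples_partial[
    match(admrs$admr_id, profiles$admr_id)]
  np[is.na(np)] <- 0L
  out <- data.table::copy(admrs)
  out[, "flag_panel_partial" := panel_size > 0L &
        np > max_fraction * panel_size]
  out[]
}

#' Flag aDMRs near known imprinted regions
#'
#' Flags `imprinted` when the gap between the aDMR and any imprinted
#' interval is at most `window_bp` (10 kb); overlap counts as distance 0.
#'
#' @param admrs aDMR table.
#' @param imprinted_regions interval table (chrom, start, end); may be empty.
#' @param window_bp maximum distance in bp.
#' @return aDMR table with logical column `flag_imprinted`.
#' @export
exclude_imprinted <- function(admrs, imprinted_regions, window_bp = 10000L) {
  admrs <- .with_admr_id(admrs)
  flag <- rep(FALSE, nrow(admrs))
  imprinted_regions <- data.table::as.data.table(imprinted_regions)
  if (nrow(admrs) && nrow(imprinted_regions)) {
    d <- .distance_to_nearest(.as_granges(admrs),
                                          .as_granges(imprinted_regions))
    q <- S4Vectors::queryHits(d)
    flag[q] <- S4Vectors::mcols(d)$distance <= window_bp
  }
  out <- data.table::copy(admrs)
  out[, "flag_imprinted" := flag]
  out[]
}

#' Tumor-specific aDMRs after the full exclusion cascade
#'
#' Applies all three flags and retains aDMRs carrying none of them. An aDMR
#' failing several filters is removed once but counted under every flag.
#'
#' @param tumor_admrs,normal_admrs aDMR tables.
#' @param panel normal WGBS panel records; may be empty.
#' @param imprinted imprinted-region intervals; may be empty.
#' @param panel_size panel sample count; defaults to the distinct sample ids
#'   present in `panel`.
#' @return list(admrs = retained aDMR table with all flag columns,
#'   flagged = full flagged table, report = per-stage removal counts).
#' @export
tumor_specific_admrs <- function(tumor_admrs, normal_admrs, panel, imprinted,
                                 panel_size = NULL) {
  panel <- data.table::as.data.table(panel)
  if (is.null(panel_size))
    panel_size <- length(unique(panel$sample_id))
  x <- exclude_matched_normal(tumor_admrs, normal_admrs)
  prof <- partial_methylation_profile(x, panel)
  x <- exclude_panel_partial(x, prof, panel_size)
  x <- exclude_imprinted(x, imprinted)
  keep <- !(x$flag_matched_normal | x$flag_panel_partial | x$flag_imprinted)
  report <- data.table::data.table(
    stage = c("input", "matched_normal", "panel_partial", "imprinted",
              "removed_any", "retained"),
    n = c(nrow(x), sum(x$flag_matched_normal), sum(x$flag_panel_partial),
          sum(x$flag_imprinted), sum(!keep), sum(keep)))
  list(admrs = x[keep], flagged = x[], report = report[])
}
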