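# Truth-set audit of aDMR recovery on synthetic data.

#' Sensitivity and precision of aDMR calls against a planted truth set
#'
#' A planted region counts as recovered when at least `min_cpg_frac` of its
#' CpG sites fall inside called aDMRs; a call counts as true when it
#' overlaps at least one planted region by 1 bp or more.
#'
#' @param admrs called aDMR table (chrom, start, end).
#' @param truth planted regions (chrom, start, end).
#' @param sites CpG site table (chrom, pos), e.g. the output of
#'   [test_per_cpg()].
#' @param min_cpg_frac recovery threshold on the fraction of covered CpGs.
#' @return list(sensitivity, precision, per_region coverage fractions).
#' @export
audit_admr_recovery <- function(admrs, truth, sites, min_cpg_frac = 0.5) {
  admrs <- data.table::as.data.table(admrs)
  truth <- data.table::as.data.table(truth)
  sites <- data.table::as.data.table(sites)
  cover <- rep(0, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    s <- sites[sites$chrom == truth$chrom[i] & sites$pos >= truth$start[i] &
                 sites$pos < truth$end[i]]
    if (!nrow(s)) next
    inside <- vapply(s$pos, function(p)
      any(admrs$chrom == truth$chrom[i] & admrs$start <= p & admrs$end > p),
      logical(1))
    cover[i] <- mean(inside)
  }
  true_call <- vapply(seq_len(nrow(admrs)), function(i)
    any(truth$chrom == admrs$chrom[i] & truth$start < admrs$end[i] &
          truth$end > admrs$start[i]), logical(1))
  list(sensitivity = if (nrow(truth)) mean(cover >= min_cpg_frac) else NaN,
       precision = if (nrow(admrs)) mean(true_call) else NaN,
       per_region = cover)
}
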