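# Per-CpG haplotype methylation calls: validation, strand merge, consensus
# frequencies, phasing rate, and TSV IO.
#
# A call table is a data.table with columns
#   chrom (character), pos (integer, 0-based plus-strand C of the CG dyad),
#   strand ("+"/"-"), haplotype ("1","2","unphased"),
#   n_methylated (integer), n_total (integer).
# Coordinates are 0-based half-open throughout the package; a CpG occupies
# [pos, pos + 2).

#' Validate a per-CpG haplotype call table
#'
#' Checks column presence, count conservation (methylated <= total),
#' non-negative coordinates and legal strand/haplotype codes. Duplicate
#' (chrom, pos, strand, haplotype) rows are an input error, not merged.
#'
#' @param calls data.table of per-CpG calls.
#' @return The validated table, invisibly.
#' @export
validate_cpg_calls <- function(calls) {
  need <- c("chrom", "pos", "strand", "haplotype", "n_methylated", "n_total")
  .assert(all(need %in% names(calls)),
          "call table missing columns: %s",
          paste(setdiff(need, names(calls)), collapse = ", "))
  bad <- which(calls$n_methylated > calls$n_total | calls$n_methylated < 0)
  if (length(bad)) {
    stop(sprintf("methylated > total (or negative) at %s:%d",
                 calls$chrom[bad[1]], calls$pos[bad[1]]), call. = FALSE)
  }
  .assert(all(calls$pos >= 0), "negative CpG position")
  .assert(all(calls$strand %in% c("+", "-")), "strand must be '+' or '-'")
  .assert(all(calls$haplotype %in% c("1", "2", "unphased")),
          "haplotype must be '1', '2' or 'unphased'")
  dup <- duplicated(calls[, c("chrom", "pos", "strand", "haplotype")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate call at %s:%d strand %s haplotype %s",
                 calls$chrom[i], calls$pos[i], calls$strand[i],
                 calls$haplotype[i]), call. = FALSE)
  }
  invisible(calls)
}

#' Normalize minus-strand CpG coordinates to the plus-strand C
#'
#' Minus-strand records of a CG dyad are reported at the G (pos + 1 relative
#' to the plus-strand C). Subtracting 1 keys both strands of one CpG to the
#' same coordinate so the strand merge is a pure group-by. Records already on
#' the plus strand pass through. A minus-strand record at pos 0 has no valid
#' plus-strand C and is an error.
#'
#' @param calls call table (see [validate_cpg_calls()]).
#' @return Call table with minus-strand positions shifted to the dyad C.
#' @export
normalize_minus_strand <- function(calls) {
  calls <- data.table::as.data.table(calls)
  minus <- calls$strand == "-"
  if (any(minus & calls$pos == 0)) {
    i <- which(minus & calls$pos == 0)[1]
    stop(sprintf("minus-strand record at %s:0 cannot be normalized",
                 calls$chrom[i]), call. = FALSE)
  }
  out <- data.table::copy(calls)
  out[minus, "pos"] <- out$pos[minus] - 1L
  out
}

#' Merge the two strands of each CpG into a consensus call
#'
#' Sums methylated and total read counts over both strands of the CG dyad,
#' yielding one record per (chrom, pos, haplotype) with strand set to '+'.
#' Input minus-strand coordinates must already be normalized (see
#' [normalize_minus_strand()]); the merge itself is a group-by sum, so it is
#' idempotent and conserves counts globally and per site.
#'
#' @param calls call table with dyad-normalized coordinates.
#' @return Strand-merged call table sorted by (chrom, pos, haplotype).
#' @export
merge_strands_to_consensus <- function(calls) {
  calls <- data.table::as.data.table(calls)
  n_methylated <- n_total <- chrom <- pos <- haplotype <- NULL
  out <- calls[, list(strand = "+",
                      n_methylated = sum(n_methylated),
                      n_total = sum(n_total)),
               by = list(chrom, pos, haplotype)]
  data.table::setorder(out, chrom, pos, haplotype)
  data.table::setcolorder(out, c("chrom", "pos", "strand", "haplotype",
                                 "n_methylated", "n_total"))
  out[]
}

#' Consensus methylation frequency per CpG
#'
#' frequency = n_methylated / n_total on strand-merged calls. Records with
#' zero total reads carry no information; they are dropped and their count is
#' attached as attribute `n_dropped_zero_depth`.
#'
#' @param calls strand-merged call table.
#' @param sample_id identifier stored in the output records.
#' @return data.table with chrom, pos, haplotype, frequency, depth, sample_id.
#' @export
consensus_frequency <- function(calls, sample_id = "sample") {
  calls <- data.table::as.data.table(calls)
  keep <- calls$n_total > 0L
  out <- calls[keep, c("chrom", "pos", "haplotype", "n_methylated", "n_total")]
  out[, "frequency" := out$n_methylated / out$n_total]
  out[, "depth" := out$n_total]
  out[, c("n_methylated", "n_total") := NULL]
  out[, "sample_id" := sample_id]
  data.table::setattr(out, "n_dropped_zero_depth", sum(!keep))
  out[]
}

#' Fraction of covered CpG sites assigned to a haplotype
#'
#' Counts distinct (chrom, pos) sites with at least one covered record on
#' haplotype 1 or 2, over all distinct covered sites.
#'
#' @param calls call table (any strand state).
#' @return Phased fraction in [0, 1]; NaN for an empty/uncovered table.
#' @export
phased_fraction <- function(calls) {
  calls <- data.table::as.data.table(calls)
  covered <- calls[calls$n_total > 0L]
  if (nrow(covered) == 0L) return(NaN)
  sites <- unique(covered[, c("chrom", "pos")])
  phased <- unique(covered[covered$haplotype %in% c("1", "2"),
                           c("chrom", "pos")])
  nrow(phased) / nrow(sites)
}

# ---- IO ---------------------------------------------------------------------

#' Read / write the per-CpG call TSV dialect
#'
#' Tab-separated with header: chrom, start, end, strand, haplotype,
#' n_methylated, n_total; 0-based half-open, end = start + 2. Comment lines
#' starting with '#' are ignored on read and a coordinate-convention header is
#' written on write.
#'
#' @param path file path.
#' @return `read_cpg_calls()` returns a call table (column `pos` = start).
#' @export
read_cpg_calls <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  data.table::setnames(dt, "start", "pos")
  dt[, "end" := NULL]
  dt[, "haplotype" := as.character(dt$haplotype)]
  validate_cpg_calls(dt)
  dt[]
}

#' @param calls call table.
#' @rdname read_cpg_calls
#' @export
write_cpg_calls <- function(calls, path) {
  out <- data.table::as.data.table(calls)
  out <- out[, c("chrom", "pos", "strand", "haplotype",
                 "n_methylated", "n_total")]
  data.table::setnames(out, "pos", "start")
  out[, "end" := out$start + 2L]
  data.table::setcolorder(out, c("chrom", "start", "end", "strand",
                                 "haplotype", "n_methylated", "n_total"))
  writeLines("# coordinates: 0-based half-open", path)
  data.table::fwrite(out, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a nanopolish-style methylation frequency TSV
#'
#' Requires at least columns chromosome, start, end, methylated_frequency;
#' extra columns are ignored. `called_sites` (read depth), when present, is
#' kept as `depth`.
#'
#' @param path file path.
#' @param sample_id identifier attached to every record.
#' @return data.table with chrom, pos, frequency, depth, sample_id.
#' @export
read_methyl_freq <- function(path, sample_id = basename(path)) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("chromosome", "start", "methylated_frequency")
  .assert(all(need %in% names(dt)),
          "frequency table missing columns: %s",
          paste(setdiff(need, names(dt)), collapse = ", "))
  out <- data.table::data.table(
    chrom = as.character(dt$chromosome),
    pos = as.integer(dt$start),
    frequency = as.numeric(dt$methylated_frequency),
    depth = if ("called_sites" %in% names(dt)) as.integer(dt$called_sites)
            else NA_integer_,
    sample_id = sample_id
  )
  .assert(all(out$frequency >= 0 & out$frequency <= 1),
          "methylated_frequency outside [0,1]")
  out[]
}
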