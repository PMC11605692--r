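# Allele-specific expression: gene-level aggregation of phased SNP counts,
# beta-binomial deviation test from the balanced 0.5 ratio, BH-adjusted
# cohort classification, and the cis/trans phase relation between the major
# expressed haplotype and allelic promoter methylation.

#' Aggregate phased SNP counts to gene level
#'
#' With known phase the per-haplotype read sums are the sufficient statistic:
#' H1 = sum of hap1_reads, H2 = sum of hap2_reads over the gene's SNPs.
#'
#' @param snv_counts table with gene_id, hap1_reads, hap2_reads.
#' @return data.table: gene_id, n_snps, H1, H2, major_haplotype, maf.
#' @export
aggregate_gene_counts <- function(snv_counts) {
  snv_counts <- data.table::as.data.table(snv_counts)
  hap1_reads <- hap2_reads <- gene_id <- NULL
  g <- snv_counts[, list(n_snps = .N, H1 = sum(hap1_reads),
                         H2 = sum(hap2_reads)), by = list(gene_id)]
  g[, "major_haplotype" := ifelse(g$H1 >= g$H2, "1", "2")]
  g[, "maf" := pmax(g$H1, g$H2) / (g$H1 + g$H2)]
  g[]
}

# Upper tail P(X >= x) of BetaBinomial(n, mu = 0.5, rho), via the symmetric
# Beta(a, a) parameterization with a = (1/rho - 1)/2.
.bb_upper_tail <- function(x, n, rho) {
  if (x > n) return(0)
  if (x <= 0) return(1)
  a <- (1 / rho - 1) / 2
  k <- x:n
  sum(exp(lchoose(n, k) + lbeta(k + a, n - k + a) - lbeta(a, a)))
}

#' Two-sided test of allelic balance
#'
#' Tests the aggregated gene counts against BetaBinomial(H1 + H2, 0.5, rho)
#' by doubling the tail beyond max(H1, H2), capped at 1. rho = 0 reduces
#' exactly to the two-sided binomial test (by symmetry the doubled upper tail
#' equals the sum of both tails).
#'
#' @param h1,h2 per-haplotype read counts (vectorized).
#' @param rho beta-binomial dispersion in [0, 1).
#' @return two-sided p-value(s); NA when h1 + h2 = 0.
#' @export
ase_test <- function(h1, h2, rho = 0) {
  .assert(rho >= 0 && rho < 1, "rho must be in [0, 1)")
  one <- function(a, b) {
    n <- a + b
    if (n == 0L) return(NA_real_)
    x <- max(a, b)
    tail <- if (rho == 0) pbinom(x - 1L, n, 0.5, lower.tail = FALSE)
            else .bb_upper_tail(x, n, rho)
    min(1, 2 * tail)
  }
  mapply(one, h1, h2, USE.NAMES = FALSE)
}

#' Method-of-moments dispersion from null genes
#'
#' Under the null the aggregated haplotype-1 fraction has variance
#' 0.25 (1 + (n - 1) rho) / n; solving per gene and averaging gives a pooled
#' rho, floored at 0. Supply genes believed biallelic (e.g. by excluding the
#' extreme MAF tail).
#'
#' @param h1,h2 per-gene aggregated counts.
#' @return pooled rho estimate in [0, 1).
#' @export
estimate_ase_dispersion <- function(h1, h2) {
  n <- h1 + h2
  keep <- n >= 2L
  if (!any(keep)) return(0)
  p <- h1[keep] / n[keep]; n <- n[keep]
  r <- ((p - 0.5)^2 * n / 0.25 - 1) / (n - 1)
  min(max(0, mean(r)), 0.99)
}

#' Classify a cohort of genes as ASE / BAE / not testable
#'
#' Genes with TPM below `min_tpm` (1) or without phased SNP coverage are
#' not_testable. P-values are BH-adjusted across all tested genes. ASE
#' requires major-allele frequency > `maf_min` (0.65) AND adjusted p <
#' `alpha` (0.05); everything else tested is BAE.
#'
#' @param snv_counts phased SNP count table (gene_id, hap1_reads, hap2_reads).
#' @param tpm table with gene_id, tpm.
#' @param rho beta-binomial dispersion; NULL estimates it from genes with
#'   MAF <= maf_min (a null-enriched subset).
#' @param maf_min,alpha,min_tpm classification thresholds.
#' @return data.table of GeneASEResult rows: gene_id, n_snps, major_haplotype,
#'   maf, p_value, p_adj, tpm, classification.
#' @export
classify_ase_cohort <- function(snv_counts, tpm, rho = NULL,
                                maf_min = 0.65, alpha = 0.05, min_tpm = 1) {
  g <- aggregate_gene_counts(snv_counts)
  tpm <- data.table::as.data.table(tpm)
  g <- merge(tpm, g, by = "gene_id", all.x = TRUE)
  g$n_snps[is.na(g$n_snps)] <- 0L
  if (is.null(rho)) {
    nullish <- g$n_snps > 0L & g$maf <= maf_min
    rho <- if (any(nullish)) estimate_ase_dispersion(g$H1[nullish],
                                                     g$H2[nullish]) else 0
  }
  testable <- g$n_snps > 0L & g$tpm >= min_tpm & (g$H1 + g$H2) >= 1L
  p <- rep(NA_real_, nrow(g))
  p[testable] <- ase_test(g$H1[testable], g$H2[testable], rho)
  p_adj <- rep(NA_real_, nrow(g))
  p_adj[testable] <- stats::p.adjust(p[testable], method = "BH")
  cls <- rep("not_testable", nrow(g))
  cls[testable] <- ifelse(g$maf[testable] > maf_min &
                            p_adj[testable] < alpha, "ASE", "BAE")
  out <- g[, c("gene_id", "n_snps", "major_haplotype", "maf", "tpm")]
  out[, "p_value" := p]
  out[, "p_adj" := p_adj]
  out[, "classification" := cls]
  data.table::setattr(out, "rho", rho)
  out[]
}

#' Cis/trans relation between ASE and allelic promoter methylation
#'
#' The hypermethylated haplotype of a gene's promoter aDMR is the one with
#' the larger mean methylation; the relation is cis when it equals the major
#' expressed haplotype and trans otherwise. Genes that are not testable or
#' lack a promoter aDMR are unknown.
#'
#' @param gene_results output of [classify_ase_cohort()].
#' @param promoter_admrs table with gene_id, admr_id, mean_meth_h1,
#'   mean_meth_h2 (one row per gene with a promoter aDMR).
#' @return data.table: gene_id, admr_id, relation in {cis, trans, unknown}.
#' @export
methylation_phase_relation <- function(gene_results, promoter_admrs) {
  gene_results <- data.table::as.data.table(gene_results)
  promoter_admrs <- data.table::as.data.table(promoter_admrs)
  m <- merge(gene_results[, c("gene_id", "major_haplotype",
                              "classification")],
             promoter_admrs[, c("gene_id", "admr_id", "mean_meth_h1",
                                "mean_meth_h2")],
             by = "gene_id", all.x = TRUE)
  hyper <- ifelse(m$mean_meth_h1 >= m$mean_meth_h2, "1", "2")
  rel <- ifelse(is.na(m$admr_id) | m$classification == "not_testable",
                "unknown",
                ifelse(hyper == m$major_haplotype, "cis", "trans"))
  data.table::data.table(gene_id = m$gene_id, admr_id = m$admr_id,
                         relation = rel)[]
}
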