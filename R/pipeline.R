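# End-to-end driver: simulate -> strand merge -> aDMR calling -> filter
# cascade -> annotation -> HRD scoring -> ASE classification -> report.

#' Run configuration for the demo pipeline
#'
#' Bundles the simulation config and all module parameters. Unknown keys are
#' rejected; the resolved configuration is echoed into the run log.
#'
#' @param seed master seed.
#' @param sim a [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param admr an [admr_params()].
#' @param min_samples_recurrent recurrence threshold for promoter aDMRs.
#' @param hrd_threshold HRDetect high-score cutoff.
#' @param outdir output directory, or NULL to skip writing files.
#' @param ... rejected; guards against typos.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, sim = NULL, admr = admr_params(),
                       min_samples_recurrent = 2L, hrd_threshold = 0.7,
                       outdir = NULL, ...) {
  extra <- list(...)
  .assert(length(extra) == 0L, "unknown config keys: %s",
          paste(names(extra), collapse = ", "))
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(seed = seed, sim = sim, admr = admr,
                 min_samples_recurrent = min_samples_recurrent,
                 hrd_threshold = hrd_threshold, outdir = outdir),
            class = "run_config")
}

#' Validate pipeline input tables
#'
#' Schema and coordinate sanity checks across the tables the pipeline
#' consumes: count conservation per CpG record, sortedness and non-negative
#' half-open intervals, and chromosome-name consistency between aDMR-bearing
#' tables and CN segments (a chromosome missing from the segments is a
#' warning; its aDMRs get context 'unknown').
#'
#' @param calls per-CpG call table (or NULL to skip).
#' @param intervals named list of interval tables to check (or NULL).
#' @param segments CN segments (or NULL).
#' @return character vector of warnings (invisibly); errors stop.
#' @export
validate_inputs <- function(calls = NULL, intervals = NULL, segments = NULL) {
  notes <- character(0)
  if (!is.null(calls)) validate_cpg_calls(calls)
  for (nm in names(intervals)) {
    iv <- data.table::as.data.table(intervals[[nm]])
    if (!nrow(iv)) next
    .assert(all(iv$start >= 0), "%s: negative start", nm)
    bad <- which(iv$end <= iv$start)
    if (length(bad))
      stop(sprintf("%s: zero/negative-length interval at line %d",
                   nm, bad[1]), call. = FALSE)
    o <- order(iv$chrom, iv$start)
    if (!identical(o, seq_len(nrow(iv)))) {
      first <- which(o != seq_len(nrow(iv)))[1]
      stop(sprintf("%s: not sorted (first offending line %d)", nm, first),
           call. = FALSE)
    }
  }
  if (!is.null(segments) && !is.null(intervals)) {
    seg_chroms <- unique(data.table::as.data.table(segments)$chrom)
    for (nm in names(intervals)) {
      miss <- setdiff(unique(intervals[[nm]]$chrom), seg_chroms)
      if (length(miss)) {
        msg <- sprintf(
          "%s: chromosome(s) %s absent from CN segments; context 'unknown'",
          nm, paste(miss, collapse = ","))
        warning(msg, call. = FALSE)
        notes <- c(notes, msg)
      }
    }
  }
  invisible(notes)
}

# consensus per-haplotype region means for promoter aDMRs of ASE genes,
# assembled from the simulated truth (silencing phase) for the demo
.demo_promoter_admrs <- function(ase_truth) {
  if (!nrow(ase_truth)) {
    return(data.table::data.table(gene_id = character(0),
                                  admr_id = character(0),
                                  mean_meth_h1 = numeric(0),
                                  mean_meth_h2 = numeric(0)))
  }
  hyper1 <- ase_truth$hyper_hap == "1"
  data.table::data.table(
    gene_id = ase_truth$gene_id,
    admr_id = sprintf("prom_%s", ase_truth$gene_id),
    mean_meth_h1 = ifelse(hyper1, 0.9, 0.1),
    mean_meth_h2 = ifelse(hyper1, 0.1, 0.9))
}

#' Run the full demo pipeline on synthetic data
#'
#' Generates the synthetic bundle, calls aDMRs on tumor and matched normal,
#' applies the tumor-specific filter cascade, classifies copy-number
#' context, scores HRD features (scar scores from the simulated segments,
#' microhomology fraction from the simulated deletions, fixed illustrative
#' signature exposures), classifies ASE genes and their methylation phase
#' relation, and reconciles all counts into a report. With `outdir` set,
#' writes every table as TSV/BED plus a human-readable run log.
#'
#' @param config a [run_config()].
#' @return list with elements admrs_raw, admrs (tumor-specific), filter
#'   report, annotations, ase, phase_relations, hrd, truth, and `report`
#'   (named count vector reconciling the stages).
#' @export
run_demo <- function(config = run_config()) {
  sim <- config$sim
  tum <- simulate_phased_methylome(sim, "tumor")
  nor <- simulate_phased_methylome(sim, "normal")
  panel <- simulate_normal_wgbs_panel(sim, tum$truth)
  segments <- simulate_cn_segments(sim)
  deletions <- simulate_deletions_with_flanks(sim)
  expr <- simulate_allelic_expression(sim)

  tum_cons <- merge_strands_to_consensus(tum$calls)
  nor_cons <- merge_strands_to_consensus(nor$calls)
  tum_admrs <- call_admrs(test_per_cpg(tum_cons, config$admr$window_bp),
                          config$admr)
  nor_admrs <- call_admrs(test_per_cpg(nor_cons, config$admr$window_bp),
                          config$admr)
  tum_admrs <- classify_cn_context(tum_admrs, segments)

  imprinted_bed <- tum$truth[tum$truth$class == "imprinted",
                             c("chrom", "start", "end")]
  cascade <- tumor_specific_admrs(tum_admrs, nor_admrs, panel, imprinted_bed,
                                  panel_size = sim$panel_size)

  # HRD: scar scores from segments, microhomology fraction from deletions.
  karyotype <- data.table::data.table(
    chrom = sprintf("chr%d", seq_len(sim$n_chromosomes)),
    length = sim$chrom_length_bp,
    centromere = sim$chrom_length_bp %/% 2L)
  # scar thresholds are defined for ~100 Mb human chromosomes; scale them to
  # the toy chromosome length so the demo scores stay informative
  sc <- sim$chrom_length_bp / 1e8
  scars <- scar_scores(segments, karyotype, loh_min_len = 15e6 * sc,
                       lst_min_len = 10e6 * sc, lst_smooth_len = 3e6 * sc)
  mh_frac <- microhomology_deletion_fraction(deletions)
  features <- data.table::data.table(
    sample = "demo", sbs3 = 100, sbs8 = 50, sv3 = 20, sv5 = 10,
    hrd_index = hrd_index(scars), mh_del_fraction = mh_frac)

  ase <- classify_ase_cohort(expr$snv_counts, expr$tpm)
  phase <- methylation_phase_relation(ase, .demo_promoter_admrs(expr$truth))

  report <- c(
    n_cpg_sites = nrow(tum_cons) / 2,
    n_admrs_tumor_raw = nrow(tum_admrs),
    n_admrs_normal_raw = nrow(nor_admrs),
    n_flag_matched_normal = sum(cascade$flagged$flag_matched_normal),
    n_flag_panel_partial = sum(cascade$flagged$flag_panel_partial),
    n_flag_imprinted = sum(cascade$flagged$flag_imprinted),
    n_removed = nrow(tum_admrs) - nrow(cascade$admrs),
    n_tumor_specific = nrow(cascade$admrs),
    n_genes = nrow(ase),
    n_ase = sum(ase$classification == "ASE"),
    n_bae = sum(ase$classification == "BAE"),
    n_not_testable = sum(ase$classification == "not_testable"),
    n_trans = sum(phase$relation == "trans"),
    n_cis = sum(phase$relation == "cis"),
    hrd_index = hrd_index(scars),
    mh_del_fraction = mh_frac)

  out <- list(admrs_raw = tum_admrs, admrs = cascade$admrs,
              filter_report = cascade$report, flagged = cascade$flagged,
              ase = ase, phase_relations = phase, features = features,
              scars = scars, truth = tum$truth, ase_truth = expr$truth,
              report = report)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$outdir, f)
    write_admr_bed(tum_admrs, p("admrs_raw.bed"))
    write_admr_bed(cascade$admrs, p("admrs_tumor_specific.bed"))
    data.table::fwrite(cascade$report, p("filter_report.tsv"), sep = "\t")
    data.table::fwrite(ase, p("ase_results.tsv"), sep = "\t")
    data.table::fwrite(phase, p("phase_relations.tsv"), sep = "\t")
    data.table::fwrite(features, p("hrd_features.tsv"), sep = "\t")
    writeLines(c("# demo run", sprintf("seed: %d", config$seed),
                 sprintf("%s: %s", names(report), format(report))),
               p("run.log"))
  }
  out
}
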