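---
title: "Haplotype-resolved allelic methylation, HRD scoring and ASE: models and choices"
author: "admrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-resolved allelic methylation, HRD scoring and ASE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admrtools)
```

## The problem

Long-read sequencing phases most CpGs of a tumor genome onto their parental
haplotypes. That makes a new class of somatic event directly observable:
regions where the two alleles of one sample are differentially methylated
(aDMRs). Genuine tumor-specific allelic methylation must be separated from
two constitutive look-alikes — imprinting and stable random allelic
methylation — and can then be connected to its downstream consequences:
allele-specific expression (ASE), promoter hypermethylation of
homologous-recombination (HR) genes, and HR-deficiency (HRD) scores that
inform PARP-inhibitor/platinum sensitivity. This package implements that
chain as testable, file-driven components plus a synthetic-data generator
with planted ground truth.

All coordinates are 0-based half-open. A CpG is keyed to the plus-strand C
of its CG dyad; minus-strand records are normalized by `pos - 1` so the
strand merge is a pure group-by (`normalize_minus_strand()`,
`merge_strands_to_consensus()`).

## The aDMR model

Per CpG site and haplotype we observe methylated/total read counts. The
test statistic per CpG is a Wald statistic on the difference of smoothed
haplotype frequencies:

* **Smoothing.** Coverage-weighted mean of raw frequencies over CpGs within
  ±250 bp (window 500 bp, configurable). A site alone in its window keeps
  its raw frequency.
* **Variance.** For haplotype h, `v_h = p(1-p) (N_w + rho * S_w) / N_w^2`,
  with `N_w` the summed window depth and `S_w = sum n_i (n_i - 1)`. For an
  isolated site this is the familiar beta-binomial variance
  `p(1-p)(1 + (n-1) rho)/n`. For the variance only, `p` is shrunk toward
  0.5 by half a pseudo-read, so fully separated windows (p in {0, 1}) keep a
  finite, large statistic rather than dividing by zero; identical smoothed
  frequencies give p-value 1 exactly.
* **Dispersion.** `rho` is pooled per chromosome by method of moments from
  *cross-haplotype* differences: under the allelic null both haplotypes
  share the site frequency, so between-site heterogeneity (which is large —
  methylation is bimodal) cancels in `p1 - p2` and
  `E[(p1-p2)^2] = p(1-p)[(1+(n1-1)rho)/n1 + (1+(n2-1)rho)/n2]`. Sites whose
  squared difference exceeds the 99.9% chi-square(1) envelope of its null
  sampling variance are treated as allelic signal and excluded before
  pooling; `rho` is floored at 0. An earlier estimator based on deviations
  from the smoothed mean absorbed between-site heterogeneity and inflated
  `rho` by an order of magnitude; the cross-haplotype form is the reason
  the caller has useful power at ~30x per haplotype.
* **Segmentation.** Maximal runs of consecutive CpGs with p < 1e-5, runs
  merged across gaps <= 100 bp; regions kept with >= 3 CpGs, >= 50 bp, and
  >= 50% significant CpGs. These mirror the defaults of the standard
  smoothing-based DMR callers this module emulates; it is a documented
  equivalent, not a bit-compatible clone of any of them. The allelic
  difference reported per region is the unweighted mean of *raw*
  frequencies (so the `|diff_methyl| >= 0.15` cutoff keeps its plain
  interpretation), and the delta filter is applied last.

Null calibration was checked by simulation: at 30x/30x per site and rho = 0,
Pr(p < 0.05) is within ±0.01 of 0.05 (see `test-admr.R`), and 100 seeded
no-signal genomes of 5,000 CpGs produce zero called aDMRs.

## The filter cascade

Three flags, applied independently and removed once at the end (so they
commute; `tumor_specific_admrs()` reports counts per flag):

1. **Matched normal**: any >= 1 bp overlap with an aDMR called in the
   matched normal. The reciprocal-50% rule is deliberately *not* used here;
   it belongs to genomic-region annotation.
2. **Panel partial methylation**: in each normal WGBS panel sample, CpGs
   with depth >= 5 inside the aDMR are evaluable; a sample with >= 5
   evaluable CpGs counts as partially methylated when *more than* 60% of
   them have frequency in [0.35, 0.65] (endpoints inclusive — the wording
   asymmetry between "between" and "more than" is preserved). The aDMR is
   flagged when *more than* 1% of panel samples are partial (e.g. 3 of 267
   flags, 2 of 267 does not). An empty panel flags nothing.
3. **Imprinting**: distance <= 10 kb to any known imprinted region
   (overlap = 0). The imprinted-region list is an input; the package does
   not discover imprinted loci.

## Annotation

Promoters are [TSS-1500, TSS+500) strand-aware; polyA flanks ±500 bp;
feature overlap uses the either-side reciprocal-50% rule (pair reported
when the overlap covers >= 50% of *either* interval), implemented on an
interval index and validated against an all-pairs scan. Zero-length
intervals are rejected — a fraction of zero length is undefined. Mean
region methylation is unweighted by depth ("average methylation" is read
literally); a depth-weighted variant sits behind a flag. "Recurrent"
promoter aDMRs require hits in >= 2 distinct samples by default — the
cutoff is not externally defined anywhere we could anchor it, so it is a
config-exposed assumption.

## HRD scoring

The six features are SBS3, SBS8, SV3, SV5 exposures (inputs — signature
fitting is out of scope), the HRD index, and the microhomology deletion
fraction:

* **Scar scores.** The composition (HRD index = LOH + TAI + LST) is fixed;
  the three components use the field-standard numeric definitions, all
  config-exposed: LOH = interstitial minor_cn = 0 segments > 15 Mb; TAI =
  allelically imbalanced segments reaching a chromosome end without
  crossing the centromere; LST = breakpoints between adjacent >= 10 Mb
  segments per arm after absorbing < 3 Mb segments into their longer
  neighbor. Equal-state neighbors are merged first, making the scores
  invariant under state-preserving subdivision. On the 1 Mb toy genome the
  demo scales these thresholds by chromosome-length ratio.
* **Microhomology.** A deletion's homology is the longer of the prefix
  match (deleted sequence vs right flank) and suffix match (vs left flank),
  capped at the deletion length. The fraction counts deletions > 3 bp with
  homology >= 1 over *all* deletions; the "> 3 bp" clause is read as a
  numerator qualifier. A flag switches the denominator to > 3 bp deletions
  only.
* **Scoring.** Features are ln(x+1)-transformed (handles zero exposures)
  and z-normalized within the cohort by default; cohort-relative scores
  depend on cohort composition, so single-sample scoring requires
  explicitly supplied external means/SDs (`center`/`scale`). The logistic
  model uses the published intercept -3.364 and coefficients 1.611, 0.091,
  1.153, 0.847, 0.667, 2.398 in the order above; "high" means score >= 0.7.

HR-gene promoter methylation: a promoter CpG is "methylated" when its tumor
frequency strictly exceeds the matched-normal mean + 1 SD at that site; the
reported number is the fraction of methylated CpGs, with LOH status from
the covering CN segment.

## ASE

With known phase, the per-haplotype read sums are the sufficient statistic,
so SNP counts are aggregated per gene rather than meta-analyzed per SNP.
The two-sided test doubles the Beta-Binomial(n, 0.5, rho) tail beyond
max(H1, H2), capped at 1; rho = 0 reduces *exactly* to the binomial test
(verified against full enumeration to 1e-10 for totals <= 500). rho, when
not supplied, is method-of-moments estimated from the null-enriched genes
(MAF <= 0.65). Classification: ASE iff MAF > 0.65 and BH-adjusted p < 0.05
and TPM >= 1; genes below 1 TPM or without phased SNPs are not testable.
The cis/trans relation compares the hypermethylated promoter haplotype
(larger aDMR mean) to the major expressed haplotype.

## What the synthetic data emulates — and what it does not

The generator's defaults state the tested regime: 2 chromosomes x 1 Mb x
5,000 CpGs, Poisson 30x per haplotype split evenly over strands, 50 planted
tumor-specific aDMRs of 20 CpGs at allelic delta 0.5, 5 imprinted regions
(one near-fully methylated haplotype in tumor *and* normal), 5 constitutive
random-ASM regions (allelic in both roles), a 30-sample WGBS panel
partially methylated at every imprinted locus, 200 genes (20 ASE at MAF
0.8, ~200 reads), 30% LOH genome fraction, and 500 deletions with
microhomology planted at 40%.

Choices worth knowing:

* **Background bimodality.** Per-CpG background methylation is drawn from
  an equal mixture of Beta(0.5, 10) and Beta(10, 0.5) shared by both
  haplotypes — a flat 50% background would make the partial-methylation
  filter vacuous. Sites are independent; real methylomes have spatial
  domain structure the generator does not model.
* **Planted aDMRs are gains.** Planted regions draw their background from
  the unmethylated component and add the delta to haplotype 1, so the
  realized allelic difference equals the configured one exactly (a shift
  applied on a bimodal background would be clipped at 1 half the time and
  cancel under smoothing).
* **Placement.** One region per equal CpG-count slot with 35 CpGs of
  margin, so planted regions of different classes stay clear of each
  other's 10 kb imprinting window at default density; an impossible packing
  raises an explicit error.
* **Shared world.** CpG positions, background frequencies and planted
  regions derive from the seed alone; tumor and normal roles differ only in
  read noise (and in tumor-specific regions being background in the
  normal). This is what makes matched-normal filtering meaningful.
* **Microhomology planting.** The planted fraction applies over *all*
  deletions, with planted deletions forced > 3 bp, so the downstream
  measured fraction is directly comparable to the configured one.
  Homology-free deletions force a mismatch at both breakpoint-adjacent
  bases.
* **ASE silencing phase.** 75% of planted ASE genes put the hypermethylated
  promoter haplotype on the minor expressed allele (silencing in trans),
  mirroring the direction reported for real tumors; this is what the
  trans > cis acceptance check exercises.

A green test on this generator establishes internal correctness of the
statistics and plumbing under the stated model — binomial counts, exact
phasing, independent sites. It does not establish performance on real data
with read-level errors, phasing switch errors, spatially correlated
methylation, or subclonal tumors.

## Numerical choices and degenerate inputs

* Variance shrinkage by half a pseudo-read (above) instead of a hard floor.
* Two-sided p-values by tail doubling, capped at 1 (both the Wald-normal
  and beta-binomial paths).
* Zero-variance features standardize to z = 0 with a warning; cohorts of
  fewer than 2 samples refuse cohort standardization.
* Zero-depth CpG records are dropped (and counted) before frequencies;
  duplicate (site, haplotype) rows are an error, never silently merged.
* No deletion > 3 bp makes the microhomology fraction undefined: reported
  as 0 with a warning rather than NA, so downstream scoring stays total.
* `run_demo()` uses fixed illustrative SBS/SV exposures for its single
  sample; exposures are inputs everywhere else.

## Known limitations

* The aDMR caller is a documented equivalent of smoothing-based DMR
  callers, not a reimplementation of any specific one; region boundaries
  can splinter at isolated CpGs (the recovery audit therefore counts
  covered planted CpGs, not exact boundary matches).
* Cohort-relative HRDetect scores shift when the cohort changes; use
  external moments for stable single-sample scores.
* The TAI definition requires segments to reach the chromosome end exactly
  (telomere-adjacent unsegmented gaps are not bridged).
* The per-SNP meta-analysis mode of ASE aggregation is out of scope, as are
  read alignment, variant calling, phasing itself, SV calling and
  mutational-signature fitting.
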