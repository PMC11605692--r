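Package: admrtools
Title: Haplotype-Resolved Allelic Methylation, HRD Scoring and Allele-Specific Expression
Version: 0.1.0
Authors@R: person("POG", "Methylation", email = "devnull@example.org", role = c("aut", "cre"))
Description: Detection of allelically differentially methylated regions (aDMRs)
    from phased per-CpG methylation calls, a three-stage filter cascade that
    reduces raw tumor aDMRs to tumor-specific aDMRs (matched-normal overlap,
    partial methylation in a normal WGBS panel, proximity to imprinted loci),
    strand-aware promoter construction and reciprocal-overlap region
    annotation, genomic-scar features (LOH, TAI, LST), microhomology deletion
    fraction and HRDetect logistic scoring, and beta-binomial allele-specific
    expression classification with cis/trans phasing against allelic promoter
    methylation. A synthetic-data module generates ground-truth-annotated
    phased methylomes, normal panels, copy-number segments, deletions and
    allelic RNA counts so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
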