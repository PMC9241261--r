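Package: oncopanelQC
Title: Quality Control and False-Positive Analysis for Oncopanel Sequencing of FFPE Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify technical artifacts introduced by formalin
    fixation and paraffin embedding (FFPE) in targeted oncology panel
    sequencing. From per-sample VCFs and panel/region definitions the package
    builds consensus known-variant sets, identifies and classifies
    FFPE-induced false positives (hydrolytic deamination G:C>A:T, oxidative
    G:C>T:A, indels), computes false-positive rates per million targeted
    bases, detects cross-individual contamination from VAF histograms,
    categorizes block sections into surface and inner groups, and runs the
    group comparisons (Welch's t, Yates-corrected chi-squared) used in
    oncopanel QC studies. A seeded synthetic-cohort generator emulates the
    full study design so the pipeline is testable end to end without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
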