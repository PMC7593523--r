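Package: dmrkit
Title: Differential Methylation and Hydroxymethylation Region Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differentially methylated (5mC) and hydroxymethylated
    (5hmC) regions from hydroxymethylation- and methylation-sensitive tag
    sequencing (HMST-seq) three-library tag counts or from WGBS/RRBS per-base
    methylation levels. Partitions a genome into TSS, TES, gene-body,
    5'-distance and intergenic regions from a UCSC refFlat gene model,
    clusters methylated sites into methylated regions (MRs), pairs MRs across
    conditions with missing-value imputation, tests them with an exact
    enumeration of the Wilcoxon rank-sum P-value (or its large-sample
    approximation, Kolmogorov-Smirnov, or pooled-variance T-test), classifies
    direction by a relative-ratio statistic, annotates DMRs to genes, and
    summarises genome-wide methylation with relative site densities,
    hyper/hypo percentages and smoothed TSS-gene-TES meta-profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    parallel,
    graphics,
    grDevices,
    jsonlite,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
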