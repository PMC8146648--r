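Package: svadapt
Title: Structural-Variant Catalogs and Signatures of Selection and Archaic
    Introgression in Human Populations
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds non-redundant structural-variant (SV) catalogs from
    per-sample long-read callsets, classifies SV formation mechanisms
    (NAHR, VNTR, TE) from breakpoint-junction repeat profiles, runs
    permutation enrichment against annotation tracks, quality-controls
    short-read SV genotypes (missing rate, Hardy-Weinberg exact test,
    cross-dataset concordance), computes Weir-Cockerham and Hudson F_ST to
    call population-stratified SVs, and scans flanking phased SNV
    haplotypes for positive selection (EHH, iHS, XP-EHH) and archaic
    introgression (D, f_d, S*-like dynamic programming), with significance
    calibrated against coalescent simulations of a fitted demographic
    model.  A synthetic-data module generates every input with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    rtracklayer,
    knitr,
    rmarkdown
SystemRequirements: python (>= 3.8) with msprime (>= 1.0), numpy
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StructuralVariation, PopulationGenetics, Coverage, Genetics
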