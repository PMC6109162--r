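Package: andescan
Title: Selection Scans for High-Altitude Adaptation in Three-Population
    SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed Population Branch Statistic (PBS) selection scans
    for a three-population design (a focal highland group and two lowland
    groups), with Reynolds FST, empirical outlier peaks and nearest-gene
    assignment; simulation-based significance from a structured
    three-population coalescent under constant, bottleneck and
    bottleneck-plus-expansion demographies; extended haplotype
    homozygosity statistics (EHH, iHS, XP-EHH) computed from first
    principles; bootstrap confidence intervals for sample-size-weighted
    allele frequencies; and inverse-distance-weighted geographic allele
    frequency surfaces. Includes a synthetic-data generator emulating the
    hierarchical population structure so the full pipeline can be
    exercised end to end without access to restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    geosphere,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
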