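Package: crossqtl
Title: QTL Mapping and Variance Decomposition for Haploid Yeast Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative trait locus (QTL) mapping in two-parent
    haploid yeast crosses genotyped by sparse sequencing (RAD-seq style
    allele counts) and phenotyped by colony patch areas. Implements parental
    SNP table construction and progeny genotype calling from allele counts
    with the 5x confidence rule, marker and strain quality filters,
    read-depth based chromosome copy-number estimation and chromosome I
    disomy classification, nonparametric (Kruskal-Wallis rank based)
    single-locus genome scans with permutation-derived genome-wide LOD
    thresholds and split-population secondary scans, floor-aware quantile
    normalization of censored growth phenotypes, broad-sense heritability
    by variance components, per-locus genetic variance decomposition, and a
    synthetic cross simulator with known ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    car,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
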