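Package: telometry
Title: Mean Telomere Length Estimation from Whole-Genome Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates mean telomere length (MTL) from whole-genome
    sequencing reads by aligning them end-to-end to a telomeric index (a
    tiling of the telomeric repeat pattern followed by an ambiguous-base
    tail), converting telomeric read depth into a telomeric-to-genomic
    coverage ratio, and scaling by the number of chromosome ends.  Also
    provides a repeat-count comparator estimator, an Illumina-like read
    simulator that builds synthetic genomes with telomeres of known
    length, and an accuracy-evaluation harness (MRE, RMSE, R squared)
    for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
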