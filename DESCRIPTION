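Package: regstage
Title: Stage-Resolved Integration of Transcription Factor Binding and
    Expression Response
Version: 0.1.0
Authors@R:
    person("regstage", "developers", email = "regstage@example.org",
           role = c("aut", "cre"))
Description: Tools for relating stage-resolved ChIP-seq binding to gene
    expression response during developmental transitions. Implements
    summit-proximity peak comparison and union merging, bootstrap
    significance for multi-set peak and gene overlaps, strand-aware
    promoter/intragenic/intergenic peak-to-gene allocation, trinary
    expression-pattern coding and grouping, binding-by-expression response
    classes, position weight matrix scanning with motif-pair
    co-localization z-scores, composite tag-density profiles around peak
    summits, and a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    withr,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    ape
Config/testthat/edition: 3
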