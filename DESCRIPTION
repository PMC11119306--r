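Package: enacmap
Title: Zone-Sector Activation Mapping for Multiplex FISH of the Extended
    Nucleus Accumbens
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Model-free regional activation analysis of multiplex RNAscope
    FISH sections of the extended nucleus accumbens. Segments DAPI-stained
    nuclei (Huang auto-threshold, distance-transform watershed, particle
    analysis), binarizes signal channels by a Renyi-entropy criterion,
    calls per-cell Fos/Drd1/Drd2 positivity from area-overlap fractions,
    parcellates cells into a polar plane-zone-sector grid anchored on the
    anterior commissure, and computes per-region statistics: Fos-fraction
    t maps with Benjamini-Hochberg FDR, dopamine-receptor composition
    tests, scratch-Fos Spearman correlation maps, and hierarchical
    clustering of regional response profiles. Includes a ground-truthed
    synthetic-data generator (cell tables, rendered section images, and
    scratch-bout series) so the whole pipeline is testable without raw
    imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
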