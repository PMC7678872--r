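Package: alphaflash
Title: Simulation and Event Calling for Single-Cell Glucagon Release TIRF Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying glucagon secretion from single pancreatic
    alpha cells imaged by TIRF microscopy with a pH-sensitive granule reporter.
    Provides a ground-truth-annotated simulator of fusion-flash movies under
    glucose ramp and pharmacology protocols, grid-based release-event calling
    with same-frame spillover rejection, normalization to events per 100 square
    micrometres per minute, dose-response threshold detection, and the
    associated statistical procedures (Student's t, one- and two-way ANOVA,
    Scheffe post-hoc means comparison) implemented from first principles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
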