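Package: accost
Title: Differential Chromatin Contact Detection with Distance-Specific
    Size Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns statistical confidence estimates to differences in Hi-C
    contact counts between two conditions while normalizing away the genomic
    distance effect. Counts are modeled as negative binomial with a mean that
    factorizes into ICE locus-specific biases, distance-specific size factors
    and a normalized contact intensity; the variance adds a smooth raw
    variance function of the normalized intensity, estimated from
    same-distance neighborhoods. Differences are scored by a conditional
    exact test on the pooled per-condition counts given their total, with
    Benjamini-Hochberg control of the false discovery rate. Includes a
    simulator of distance-decaying contact matrices for null calibration and
    power studies, and quantile-quantile / fold-change diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
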