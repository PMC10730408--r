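Package: larvascreen
Title: High-Throughput Behavioral Phenotyping and Genetic Screening for
    Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying larval zebrafish behavior from
    multi-well tracking data and for running mutant-versus-sibling
    genetic screens on the resulting metrics. Encodes a two-hour
    four-assay stimulus paradigm (visual motor response, light flash,
    dark flash, acoustic startle) as a queryable timeline, tracks larvae
    in grayscale frames (centroid, five tail points, orientation, body
    curvature), detects swim bouts and classifies startle responses
    (O-bend, short- and long-latency C-starts), computes a 94-metric
    behavioral profile per larva including habituation, prepulse
    inhibition and startle sensitivity, and implements two-experiment
    reproducibility filtering, sibling normalization and
    Bonferroni-corrected screening statistics. A synthetic cohort
    simulator with genotype-dependent behavioral parameters exercises
    the full pipeline and supports parameter-recovery validation
    without recorded video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
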