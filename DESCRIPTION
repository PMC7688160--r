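Package: valvequant
Title: Quantitative Phenotyping of Murine Calcific Aortic Valve Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementations of the quantitative phenotyping
    computations used to characterise calcific aortic valve disease (CAVD)
    in mouse models: R-wave gated Doppler hemodynamics (peak systolic
    velocity, simplified-Bernoulli mean pressure gradient, severity
    classification), HSL colorimetric segmentation of Masson's trichrome
    sections with leaflet morphometrics, DAPI nucleus segmentation
    (fuzzy c-means, watershed, concave-point splitting) with
    immunofluorescence marker quantification, delta-Ct qPCR normalisation
    against the geometric mean of two housekeeping genes, and a
    normality-driven parametric/non-parametric test-selection engine with
    Tukey and Dunn post-hoc corrections. A synthetic-data generator
    emulates all four input modalities with known ground truth so that
    every stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
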