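Package: hergqsar
Title: hERG Liability Prediction by Combining Hypothesis Networks, Random
    Forests and Structural Alerts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Binary classification of hERG potassium-channel inhibition from
    2D chemical structure. Implements a self-organising hypothesis network
    (SOHN) classifier over typed atom-pair features, a random forest over
    physicochemical descriptors and circular fingerprints with a
    similarity-aware confidence score, and a structural-alert expert
    surrogate, together with bioactivity curation rules (threshold
    binarisation, conservative call merging, temporal splits), three
    model/data combination strategies (source-weighted training,
    confidence-threshold fallback to the expert, most-confident consensus),
    confusion-matrix evaluation metrics, and a synthetic two-source molecule
    generator with planted atom-pair toxicophores for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    Matrix,
    ranger,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
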