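Package: fbacsp
Title: Filter-Bank Adaptive and Common Spatial Patterns for Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes motor-imagery EEG trials with a filter-bank spatial-filtering
    pipeline that combines classical common spatial patterns (CSP, one-vs-rest per
    sub-band) with adaptive spatial patterns (ASP): single spatial weight vectors,
    one per sub-band and class pair, optimized by a local-best particle swarm to
    minimize the within-class over between-class scatter of log band-energy
    features. Features from nine 4 Hz sub-bands are screened by mutual-information
    best-individual-feature selection, pooled, reduced by decision-tree recursive
    feature elimination, and classified by a random forest. Includes a synthetic
    motor-imagery EEG generator with controllable spatial-contrast and band-energy
    class effects, and interpretation utilities (per-band mutual-information
    summaries and exact Shapley attributions for small feature sets).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    rpart,
    randomForest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
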