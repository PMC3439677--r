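Package: coregpeaks
Title: Integrative Classification of Weak Co-Regulator ChIP-seq Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies functional co-regulator (e.g. SRC-1/NCOA1) binding
    sites from weak ChIP-seq signal by pooling candidate peaks from several
    peak callers and classifying each candidate with a Bernoulli naive Bayes
    model over 67 binary features drawn from four information sources:
    trigram presence in the summit-centered sequence window, predicted
    nucleosome occupancy, overlap with the primary transcription factor's
    (ERalpha) binding peaks, and proximity to genes whose estrogen response
    depends on the co-regulator. Includes a self-training semi-supervised
    variant, an L1 (city-block) k-means baseline, per-feature ROC
    separability ranking, position-weight-matrix scanning for estrogen
    response element (ERE) containment, and a fully synthetic data generator
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
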