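Package: medimcrypt
Title: Chaotic Encryption and Fuzzy Convolutional Classification of
    Medical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Privacy-preserving toolkit for 8-bit grayscale medical
    images. Implements a chaotic stream cipher that combines extended
    zigzag confusion (any start corner, non-square matrices) with
    two-pass XOR diffusion keyed by logistic-map keystreams, optionally
    preceded by block-wise autoencoder compression; cryptanalysis
    metrics (Shannon entropy, adjacent-pixel correlation, NPCR, UACI);
    principal-component reduction with explained-variance component
    selection; K-means intensity segmentation; and a fuzzy
    convolutional neural network for binary normal/abnormal
    classification. Seeded synthetic brain phantoms make every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
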