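Package: qrstore
Title: QR-Coded Storage and Similarity Retrieval of Medical Images
Version: 0.1.0
Authors@R: person("qrstore", "developers", role = c("aut", "cre"),
    email = "maintainers@qrstore.invalid")
Description: A single-process toolkit for storing and retrieving medical
    images through QR symbols.  Images are normalized, segmented and
    summarized as intensity/shape/texture features; feature histograms are
    compared with the Bhattacharyya coefficient; a modified t-SNE embeds
    records using Bhattacharyya input distances and a Bregman-divergence
    objective (classical Gaussian/KL t-SNE is retained as a baseline mode);
    images are compressed by truncated SVD; records are encoded into QR
    symbols with Reed-Solomon error correction and kept in a
    similarity-mapped index where more than 70 percent similarity triggers
    tagging of a near-duplicate instead of a new symbol.  Includes a
    synthetic phantom-image generator so the full pipeline is testable
    offline, plus standard evaluation metrics and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
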