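Package: songpheno
Title: Automated Phenotyping of Zebra Finch Song
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fully automated analysis of zebra finch song recordings:
    amplitude-derivative syllable segmentation with shared-threshold optimization,
    unsupervised syllable labeling by nonlinear embedding and hierarchical
    density-based clustering, interpretable song-phenotype features spanning
    syntax (transition-matrix entropy rate, repetition bouts, introductory-note
    and call heuristics), timing (duration-distribution entropies, rhythm
    spectrograms, rhythm entropy, peak-frequency variability) and acoustics
    (frame-level features summarized into a 55-dimensional phenotype vector),
    and distribution-based song-similarity scoring built on a triplet-loss
    syllable embedder compared with exact Earth Mover's Distance and Maximum
    Mean Discrepancy. Includes a deterministic synthetic song generator for
    validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
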