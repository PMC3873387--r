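Package: icnet
Title: Inflammation-to-Cancer Regulatory Network Dysregulation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Reconstructs phenotype-specific transcription-factor regulatory
    networks from expression matrices using a Gaussian-kernel mutual
    information estimator with permutation-calibrated significance and data
    processing inequality pruning; clusters network collections with a
    network-level topological overlap similarity; identifies TF-gene
    relationships whose mutual information differs significantly between an
    inflammatory and a cancerous condition via a pooled permutation null with
    false discovery rate control; and selects core transcription factors by
    degree and inflammation/cancer composition-ratio thresholds. Ships a
    linear-Gaussian synthetic-data generator with planted regulatory
    structure so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
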