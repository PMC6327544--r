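Package: peakcast
Title: Cell Type-Specific Transcription Factor Binding Prediction from
    Chromatin Accessibility and Motif Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts cell type-specific transcription factor binding sites
    from chromatin accessibility (DNase-seq/ATAC-seq fold-enrichment
    coverage) and motif scans. The genome is tiled into 50-bp bins, per-bin
    accessibility and position weight matrix features are summarised over an
    odd number of adjacent bins, and a two-class classifier built as a
    product of independent exponential-family densities is trained by the
    weighted discriminative maximum conditional likelihood principle.
    Training negatives come from three chromosome-stratified sampling
    schemas and are refined by five rounds of iterative hard-negative
    mining; predictions from the resulting classifier ensemble are turned
    into per-window binding probabilities and narrowPeak calls.  Includes a
    synthetic-data generator with known ground truth, challenge-style
    evaluation metrics (AUC-PR with continuous interpolation, AUC-ROC,
    recall at fixed FDR, peak Jaccard), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
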