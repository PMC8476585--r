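Package: ss3fold
Title: Alignment-Free Protein Fold Classification from Secondary-Structure Strings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies protein structural folds from per-residue three-state
    secondary-structure strings (helix/strand/coil) without any sequence
    alignment. Provides a multitask convolutional neural network with
    channel and spatial attention for joint fold and family classification,
    Grad-CAM per-residue activation maps for interpretation, UMAP and
    Gaussian-mixture clustering of learned embeddings, and an open-set
    autoencoder that flags families likely to adopt novel folds via a
    masked reconstruction error, extreme-value threshold calibration, and a
    per-cluster fold-assignment score. Includes a synthetic fold-grammar
    simulator so the full workflow can be exercised and validated without
    external structural data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    jsonlite,
    yaml,
    withr,
    mclust
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
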