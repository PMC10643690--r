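Package: phenomol
Title: Contrastive Co-Embedding of Microscopy Images and Chemical Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint embedding of multi-channel fluorescence microscopy images
    (Cell-Painting-style, five channels) and small-molecule chemical
    structures into a shared unit-norm space by multi-modal contrastive
    learning. Implements the InfoNCE and InfoLOOB objectives, continuous
    modern Hopfield retrieval, residual image and fingerprint-based structure
    encoders trained with decoupled weight decay and cosine-annealed warm
    restarts, Morgan-style circular and combined fingerprint featurization,
    molecule-grouped and scaffold data splits, and the downstream evaluation
    stack: cross-modal top-k retrieval with exact Clopper-Pearson intervals,
    zero-shot image-to-image classification with plate-effect filtering, and
    linear probing of frozen representations. A synthetic paired-data
    generator with a controllable shared latent signal makes the whole
    pipeline runnable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    EBImage,
    glmnet,
    igraph,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
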