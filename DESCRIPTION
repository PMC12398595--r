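Package: melanogan
Title: Semi-Supervised GANs with Bee-Colony Hyperparameter Tuning for
    Melanoma Feature Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements a semi-supervised generative adversarial network
    (SS-GAN) for binary melanoma versus non-melanoma classification of
    image-derived feature vectors. The discriminator classifies samples
    into three classes (melanoma, non-melanoma, fake) and is trained with
    a hybrid objective combining supervised and unsupervised adversarial
    losses with a generator reconstruction penalty, consistency
    regularization under feature-space augmentation, and confidence-based
    pseudo-labeling of unlabeled samples. Single-head scaled dot-product
    self-attention prefixes both networks. Hyperparameters are optimized
    with a mutual-learning artificial bee colony (ML-ABC) over a
    random-key encoding of mixed continuous/categorical search spaces.
    Includes a synthetic multi-modal feature generator, stratified
    splitting and oversampling utilities, classification metrics for
    imbalanced data (F-measure, G-means, TPR/FNR, AUC), and distribution
    metrics for generator quality (MMD, KL divergence, sliced Wasserstein
    distance, mode score).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    FNN,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
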