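Package: nitrosite
Title: Nitrotyrosine Site Prediction from Protein Sequence Windows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts nitrated tyrosine (nitrotyrosine) sites from protein
    sequence. Tyrosine-centred windows are extracted with terminal gap
    padding and encoded under four schemes (position one-hot binary,
    AAindex physicochemical properties, composition of k-spaced amino
    acid pairs, and k-mer composition); features are ranked by
    random-forest recursive feature elimination and the best top-N subset
    per encoding is chosen on a 50-step grid by cross-validated AUC; one
    probability forest is trained per encoding and the four probability
    scores are fused by a convex linear combination whose weights can be
    optimized on out-of-fold predictions. Includes sensitivity,
    specificity, accuracy, Matthews correlation and ROC/AUC evaluation
    with stratified five-fold cross-validation, a synthetic planted-motif
    sequence generator for end-to-end benchmarking without external data,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
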