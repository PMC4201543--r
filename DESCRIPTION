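Package: caspcleave
Title: Caspase Cleavage-Site Prediction from Sequence and Predicted Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts caspase cleavage sites in protein sequences. Builds a
    background-normalized log2 position weight matrix over the P5-P3' cleavage
    context from annotated substrates, constructs sliding-window negative
    training sets, trains and evaluates a random-forest classifier on PWM plus
    secondary-structure and disorder features, and applies the model to scan
    proteomes, search cleavage motifs, re-score sequence variants, and map
    predicted sites onto orthologs through pairwise global alignment. Includes
    a synthetic-proteome generator with a tunable cleavage-motif effect size
    for benchmarking and null calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
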