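Package: venuecast
Title: Journal Venue Recommendation from Abstracts with a Deep
    Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A publication-venue recommender for biomedical abstracts.
    Parses PMC/JATS XML into journal-labelled paper records, applies the
    standard corpus inclusion filters, represents each abstract as a
    fixed-length matrix of word2vec-style word embeddings, and classifies
    it with a three-stage one-dimensional convolutional network (ReLU,
    width-2 max pooling, fully connected and hidden layers, softmax head)
    trained by Adam on the cross-entropy loss. Ranks journals by predicted
    probability to produce a top-N recommendation list, and evaluates with
    top-N accuracy, macro/micro precision/recall/F1, and journal-size
    stratified accuracy. Includes a synthetic corpus generator with
    controllable topic separation and class imbalance so the whole
    pipeline is testable without downloads, plus a command-line interface.
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
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
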