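Package: xchar
Title: Interpretable Complex Human Activity Recognition with Temporal
    Concept Bottlenecks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Recognizes complex human activities from multivariate wearable
    sensor time series while explaining every prediction in terms of
    human-understandable concepts. A convolutional sensor-fusion front end
    and a bidirectional LSTM produce a temporal concept bottleneck that is
    trained with connectionist temporal classification (CTC) loss from
    weakly aligned concept-sequence labels (no start/end timestamps), and a
    temporal convolutional classifier predicts the complex activity from
    the bottleneck alone. Predictions are explained by a prefix beam-search
    decoding of the concept matrix together with a nearest training
    instance counterfactual under Damerau-Levenshtein distance. Includes a
    synthetic benchmark generator that concatenates concept-specific signal
    segments according to a class grammar, evaluation metrics (macro
    F1-score, concept accuracy, edit distance), and a faithfulness
    perturbation protocol.
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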