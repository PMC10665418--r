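Package: pathasv
Title: Speaker Verification Risk Analysis for Pathological Speech
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how speech pathology affects automatic speaker
    verification (ASV) and hence re-identification risk of patients in speech
    corpora. Implements a text-independent d-vector system trained with the
    generalized end-to-end (GE2E) loss: a log-mel filterbank front-end with
    energy pruning and voice activity detection, a recurrent (LSTM) encoder
    trained from scratch, sliding-window utterance embeddings, cosine scoring
    and equal error rate (EER) computation. Includes a source-filter
    synthesizer that generates pathological-speech corpora (dysglossia,
    dysarthria, dysphonia, cleft lip and palate, healthy controls) with
    microphone channel effects, plus an experiment harness with repeated
    train/test resampling, group comparisons, EER-intelligibility correlation
    and logarithmic training-size regression.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
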