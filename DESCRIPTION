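Package: speechTRF
Title: Temporal Response Functions for Speech Tracking with
    Information-Theoretic Linguistic Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying neural tracking of continuous speech
    with linear forward (encoding) models. Builds acoustic predictors
    (ERB-spaced gammatone band envelopes and rectified acoustic-edge
    spectrograms) and linguistic predictors derived from a
    frequency-weighted pronunciation lexicon (cohort-model phoneme
    probability, surprisal and entropy, log word frequency) and from a
    next-word probability provider (contextual word entropy with
    equal-duration high/low entropy conditioning). Temporal response
    functions are estimated by coordinate-wise boosting with a Hamming
    window basis, L1 loss, early stopping and cross-validated
    reconstruction accuracy; nested model ladders, feature-exclusion
    contrasts and sliding lag-window models quantify incremental
    encoding gains. Mass-univariate paired tests with threshold-free
    cluster enhancement and sign-flip permutation correction assess
    channel maps. A synthetic-data module generates Zipfian toy lexica,
    bigram-language stories with exact word entropies, ground-truth
    kernels and simulated multichannel responses for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
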