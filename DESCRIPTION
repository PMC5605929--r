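Package: adrminer
Title: Adverse Drug Reaction Extraction from Drug Reviews with Recurrent
    Networks and Conditional Random Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mining adverse drug reaction (ADR) mentions from
    free-text patient drug reviews. Implements a sequence-labelling model
    that couples stacked bidirectional recurrent encoders (LSTM or GRU)
    over word embeddings and character-level convolutional features with a
    linear-chain conditional random field decoder, trained by mini-batch
    Adam on the exact negative log-likelihood. Includes readers and
    writers for brat standoff and CoNLL token-per-line corpora, BIO span
    codecs with overlap resolution, exact and token-overlap (partial)
    span evaluation with per-sentence macro averaging, a synthetic
    annotated-review generator for fully reproducible experiments, and
    demographic group-distinct ADR term mining.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
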