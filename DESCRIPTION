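Package: lpipred
Title: Multi-Branch Convolutional Prediction of lncRNA-Protein Interactions
Version: 0.1.0
Authors@R: person("lpipred", "maintainers", email = "lpipred@example.org",
                  role = c("aut", "cre"))
Description: Sequence-based prediction of long noncoding RNA (lncRNA) to
    protein interactions. Provides FASTA/TSV dataset assembly with
    length filtering, similarity-ranked negative sampling, global and
    windowed one-hot sequence encodings over the 4-letter RNA and
    7-group reduced amino-acid alphabets, hand-designed composition and
    coding-potential features, secondary-structure and physicochemical
    propensity tracks reduced to fixed length by a cosine (Fourier)
    series, a four-branch convolutional classifier trained by
    backpropagation, a full binary-classification evaluation suite, and
    a seeded synthetic-data generator so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
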