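Package: ksclass
Title: Profile HMM Scoring and Classification of Ketosynthase Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build profile hidden Markov models from seed alignments of
    ketosynthase (KS) domains, score protein sequences with forward-algorithm
    bit scores, and classify them into animal type I fatty acid synthases
    (FAS), animal FAS-like polyketide synthases (AFPK), canonical polyketide
    synthases (PKS) and mitochondrial type II FAS using score-space rules
    (hit-score gate, y = x FAS/PKS split, FAS-score bands). Includes the
    AFPK-Finder workflow (multi-HMM score matrix, normalization, 2D
    embedding, density clustering, clade-congruence evaluation, panel
    selection and reference-guided k-nearest-neighbour classification) and a
    seeded synthetic generator of KS-like families, including interpolated
    intermediate families that emulate the FAS-PKS score continuum.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    Rtsne,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
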