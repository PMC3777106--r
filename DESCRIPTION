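Package: profscan
Title: Profile Hidden Markov Model Homology Search for DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic homology search of nucleotide sequence databases
    with profile hidden Markov models. Builds position-specific profiles from
    DNA multiple sequence alignments (or single sequences), scans long
    double-stranded targets through a staged acceleration pipeline (ungapped
    single-segment seed filter, gapped Viterbi filter, Forward/Backward
    rescoring with a composition-bias correction), and reports ranked,
    E-value-scored local hits with per-position posterior alignment
    confidence. Includes score-distribution calibration by simulation and a
    self-contained synthetic benchmark (identity-split families, background
    HMM decoys, family-pairwise and consensus baselines, ROC curves).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    stringi,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
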