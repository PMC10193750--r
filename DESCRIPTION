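Package: orfvec
Title: Coding Potential Prediction from ORF Features and Protein Paragraph Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes protein-coding transcripts (mRNAs) from long
    non-coding RNAs using a support vector machine over two kinds of
    evidence: classic sequence statistics (longest-ORF length, coverage and
    integrity, an in-frame hexamer usage log-likelihood score, Fickett
    TESTCODE, GC content, and physicochemical properties of the translated
    protein) and a 100-dimensional paragraph-vector (PV-DM) embedding of the
    protein translated from the longest ORF, learned from non-overlapping
    amino-acid 3-mers. Includes a seeded synthetic transcript simulator for
    end-to-end testing, evaluation metrics (sensitivity, specificity,
    precision, accuracy, F-score, MCC, trapezoidal AUC), ablation switches
    for each feature group, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
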