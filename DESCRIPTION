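Package: thermoscan
Title: Thermophilic Protein Classification from Sequence Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discriminates thermophilic from non-thermophilic proteins using
    sequence-derived descriptors and a support vector machine. Provides ten
    protein descriptor encodings (amino acid, dipeptide and tripeptide
    composition, dipeptide deviation from expected mean, grouped di-/tripeptide
    composition, k-spaced amino acid group pairs, conjoint triad, and
    composition/transition descriptors over thirteen physicochemical
    properties), an ensemble feature-ranking stage fused with a PageRank-style
    graph walk followed by forward-adding dimensionality selection, RBF-kernel
    SVM training with cost/gamma grid search, stratified k-fold
    cross-validation with sensitivity/specificity/accuracy reporting, and a
    synthetic sequence generator with class-conditional residue composition
    for end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
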