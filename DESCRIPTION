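Package: pum6a
Title: Positive-Unlabeled Multi-Instance Learning for m6A Detection from
    Nanopore Direct RNA Sequencing Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects N6-methyladenosine (m6A) sites from per-read feature
    tables derived from Oxford Nanopore direct RNA sequencing. Candidate
    RRACH sites are treated as bags of reads (multi-instance learning); a
    gated-attention neural network pools per-read signal and base-alignment
    features into a bag score, attention scores are calibrated to per-read
    modification probabilities by Platt scaling, and site probabilities are
    obtained with a rank-weighted Noisy-OR layer that emphasizes the most
    and least modified-looking reads. Training is positive-unlabeled:
    reliable negatives are re-selected every epoch from the unlabeled bags
    to balance the labeled positives. Includes RRACH motif scanning and
    40-feature extraction from eventalign-like and sam2tsv-like tables,
    synthetic generators for generic MIL bags and ONT-like m6A datasets,
    evaluation utilities (ROC/PR AUC, precision/recall/F1, top-N precision,
    coverage-stratified slicing), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    data.table,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
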