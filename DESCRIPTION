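Package: firePRI
Title: Reliable Negative Sample Selection for Protein-RNA Interaction
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects high-quality (reliable) negative protein-RNA pairs
    from a set of known interactions by ranking candidate pairs with an
    aggregated protein-protein similarity score (normalized
    Smith-Waterman sequence similarity, Gene Ontology term Jaccard, and
    Pfam domain Jaccard) and taking the lowest-scoring pairs.  Also
    provides the paired conjoint-triad by k-nucleotide sequence encoding
    of protein-RNA pairs, FScore filter-based feature selection, a
    cross-validated classifier evaluation harness (SVM, random forest,
    naive Bayes) with class-imbalance metrics, and a synthetic
    interactome generator with planted similarity structure for
    benchmarking negative-selection strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    graphics,
    pROC,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
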