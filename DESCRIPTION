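Package: tissuescore
Title: Cross-Platform Scoring, Calibration and Integration of Tissue
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing and integrating gene-tissue association
    evidence from heterogeneous expression platforms (microarray expression
    units, RNA-seq RPKM/FPKM, EST counts, mass-spectrometry peptide counts,
    and immunohistochemistry staining). Implements per-dataset quality
    scoring with platform-specific filtering and aggregation rules, a
    weighted multi-antibody immunohistochemistry consensus score, fold
    enrichment against a curated gold standard, score-window calibration
    curves with parametric transforms onto a unified star confidence scale,
    tissue-ontology back-mapping to a fixed set of major tissues, and
    downstream analyses of expression breadth, cross-dataset consistency and
    evidence-type overlap. A synthetic-data generator with bimodal expression
    breadth and platform-specific noise makes the full pipeline testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    minpack.lm,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
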