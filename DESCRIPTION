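Package: promscreen
Title: Promoter-Level Cell-Type Specificity Screening for CAGE Expression Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying cell-type-specific promoters from CAGE
    (cap analysis of gene expression) tag-count tables. Implements
    relative-log-expression (median-of-ratios) size factors and
    tags-per-million normalization, replicate concordance and marker-panel
    quality control, a negative-binomial exact test with Benjamini-Hochberg
    correction, a five-criterion specificity screen of a small target group
    against a large reference atlas, gene-locus collapsing with
    major/alternative-promoter classification, paired two-state differential
    expression, hierarchical-clustering report recipes, and a synthetic-data
    generator with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr
Config/testthat/edition: 3
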