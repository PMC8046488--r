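Package: gagatlas
Title: Global Aging Genes and Aging Scores from Multi-Tissue Expression Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects aging-dependent genes per tissue-cell type from
    single-cell or bulk expression atlases using a linear model with a
    continuous age covariate, selects globally aging genes by
    tissue-weighted consensus, computes a background-normalized per-cell
    aging (GAG) score, estimates age, sex and tissue-cell-type score
    effects with a centered fixed-effect model, meta-analyzes effects over
    cell categories with a DerSimonian-Laird random-effects model, and
    identifies category-specific aging genes. Includes a synthetic
    multi-tissue atlas generator with planted ground truth so every stage
    can be validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
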