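Package: netformula
Title: Network Formulaology and Pharmacology Analysis of Herbal Formulas
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Computational toolkit for network-based analysis of traditional
    herbal formulas and their molecular mechanisms: drug-likeness screening
    of formula compounds (QED desirability scoring plus Lipinski and Veber
    rule violations), binomial formula-target identification with per-target
    gene scores and per-compound chem scores, hypergeometric gene-set
    enrichment with Benjamini-Hochberg correction and shared-term
    co-association curves, KATZ and closest-distance proximity between gene
    sets on a protein-protein interaction network with seeded permutation
    nulls, and core-formula mining from prescription records via adaptive
    binarization of herb co-occurrence networks and Bron-Kerbosch maximal
    clique enumeration. Deterministic synthetic-data generators cover every
    input shape, and a command-line interface exposes each analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
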