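Package: winescape
Title: Phylogenetic Signal and Community-Function Landscapes for Wine Yeast Consortia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for two linked analyses of wine yeast collections: (1)
    estimation of phylogenetic signal (Pagel's lambda) in quantitative traits
    on an ultrametric phylogeny, with a permutation significance test, and
    phylogeny-based imputation of unobserved traits under a Brownian-motion
    model evaluated by cross-validation at increasing taxonomic exclusion
    radii; and (2) the community-function landscape framework, in which
    per-strain functional effect equations (linear models of the change in
    community function against background-community function) are fitted from
    consortium measurements and concatenated over the subset lattice to
    predict the fraction of sugars consumed by arbitrary consortia. A
    synthetic-data module generates trees, lambda-tunable traits and
    ground-truth community experiments for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    stats,
    utils,
    jsonlite
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
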