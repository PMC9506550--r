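Package: brachymet
Title: Untargeted LC-MS Metabolomics of Brachypodium Organs and Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for untargeted LC-MS metabolomics of
    Brachypodium distachyon organs (leaf, root, spike) and accessions (Bd21,
    Bd3-1). Provides exact monoisotopic mass and ppm-error arithmetic over
    elemental formulas, feature-table preprocessing (half-minimum substitution
    of below-detection-limit values, log2 transform), per-feature two-way
    block ANOVA with fold-change based selection of differentially
    accumulating metabolites, PCA, m/z annotation against a bundled
    phenylpropanoid/flavonoid compound library, mummichog-style pathway
    enrichment with Benjamini-Hochberg FDR and betweenness-based pathway
    impact, and a diagnostic neutral-loss rule engine that classifies MS/MS
    and MSn fragmentation trees into structural classes (hydroxycinnamate
    conjugates, hydroxycinnamic acid amides, flavonoid glycosides,
    proanthocyanidins) with MSI confidence levels. A synthetic data generator
    reproduces the 48-sample factorial design with known ground truth so
    every stage is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
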