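Package: hybridtrace
Title: Diagnostic SNP Panels, Admixture Footprints and Two-Species
    Distribution Models for Hybrid Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for detecting historical species
    replacement in amphibian hybrid zones from panels of species-diagnostic
    SNP markers. Covers exon-based marker design and ranking, Cohen's kappa
    diagnosticity screening, within-population Hardy-Weinberg exact tests and
    genotypic linkage disequilibrium with Benjamini-Hochberg correction,
    Barton-Gale admixture linkage disequilibrium with bootstrap confidence
    intervals, maximum-likelihood EM fitting of the admixture (STRUCTURE-type)
    model with Evanno delta-K model selection, genotype PCA with weighted
    geographic contour surfaces, and a forward-stepwise logistic two-species
    climate distribution model with AUC assessment and raster hindcasting.
    A synthetic-data module generates genotype landscapes and environmental
    tables with the statistical structure these analyses assume, so the whole
    pipeline runs and is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
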