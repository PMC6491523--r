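Package: pigdiv
Title: Genetic Diversity, Differentiation and Fingerprinting of Rice Germplasm Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the population-genetic and phenotypic characterisation of
    genebank rice collections genotyped on fixed SNP arrays. Provides genotype
    panel input/output (HapMap, dosage CSV, VCF), marker and sample quality
    control with windowed LD pruning, identity-by-state and probability-of-identity
    duplicate detection for core-collection construction, group-wise diversity
    statistics (observed and expected heterozygosity, rarefied allelic richness,
    bootstrap FIS), Weir-Cockerham FST and hierarchical AMOVA, relationship-matrix
    PCA with reference-panel projection, neighbour-joining trees with locus
    bootstrap, genetic-algorithm selection of minimal fingerprinting SNP sets,
    Rc-indel by pericarp-colour cross-tabulation, and seed-trait statistics.
    A synthetic-data module simulates structured, inbred diploid SNP panels
    (Balding-Nichols model plus selfing) so every stage is testable without
    external genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    MASS,
    jsonlite
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vcfR,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
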