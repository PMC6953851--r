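Package: diazoScreen
Title: Screening and Prioritization of Diazotrophic Plant
    Growth-Promoting Bacteria
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A complete analysis chain for culturable-microbiome strain
    screening of diazotrophic and nitrogen-scavenging bacteria:
    most-probable-number (MPN) maximum-likelihood estimation of population
    densities from serial-dilution outcomes, rep-PCR (BOX-PCR) fingerprint
    analysis with proportional band-matching tolerance, Jaccard similarity
    and UPGMA clustering, Kimura two-parameter neighbor-joining phylogeny
    with bootstrap support for 16S rRNA alignments, one-way ANOVA with
    Scott-Knott clustering of treatment means for greenhouse biomass
    trials, and a multi-trait bonitur scoring engine that ranks strains by
    their plant growth-promoting potential. A synthetic-collection
    generator with known ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Microbiome, Classification, Clustering, Phylogenetics,
    StatisticalMethod
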