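Package: mtlineage
Title: Matrilineal Phylogeography from mtDNA Variants
Version: 0.1.0
Authors@R:
    person("mtlineage", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for matrilineal phylogeography of human mitochondrial
    DNA. Parses phylotree-style rCRS-relative mutation tokens, calls variants
    against the reference, classifies substitutions by functional effect and
    applies the standard hypervariable-site exclusion filter. Assigns samples
    to haplogroups from a motif-definition tree, builds median-joining
    haplotype networks, and estimates haplogroup coalescence times with the
    rho statistic and Saillard standard errors under three molecular clocks.
    Provides population-level statistics on haplogroup frequency tables
    (principal components, Nei's dA distance, hierarchical AMOVA with Phi
    statistics, weighted-least-squares admixture proportions), Moran's I
    spatial correlograms over geographic distance classes, seeded synthetic
    data generators for every stage, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    igraph,
    ape,
    jsonlite,
    optparse,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
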