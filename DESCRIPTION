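Package: introscan
Title: Genome Scans of Introgression, Topology Weighting and Recombination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying introgression between hybridising species
    from population genomic data. Implements topology weighting of
    window-based neighbour-joining genealogies by iterative subtree sampling
    (with exact enumeration or Wilson-interval-controlled Monte Carlo),
    window estimators of admixture and divergence (fd, Patterson's D, Fst,
    dXY), crossover-rate estimation from linkage maps by local-regression
    slopes, rescaling of population recombination rates to cM/Mb, and
    genome-scan analyses relating admixture to recombination rate, gene
    density, chromosome length and chromosome fusion status. A coalescent
    synthetic-data module simulates phased multi-population haplotypes and
    window genealogies under five-taxon demographies with gamma-distributed,
    directionally biased migration, for calibration and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with the msprime and tskit libraries,
    used by the coalescent simulation module.
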