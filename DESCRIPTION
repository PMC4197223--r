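Package: popgenpipe
Title: Genome-Wide Linkage Disequilibrium, Diversity and Structure for SNP-Array Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested implementation of a complete population-genetics
    workflow for dense SNP-array genotypes of livestock populations: marker
    quality control (call rate, minor allele frequency, exact Hardy-Weinberg
    test), EM-based two-locus linkage disequilibrium (r2) with distance-binned
    decay profiles, Sved's LD-based effective population size, per-marker and
    per-individual diversity indices, identity-by-state distances with
    classical multidimensional scaling, an EM admixture model with
    cross-validated choice of K, pairwise Weir-Cockerham FST, and NeighborNet
    split networks with NEXUS export.  A seeded synthetic-genotype generator
    (Balding-Nichols structure, admixed genomes, forward Wright-Fisher
    recombination) provides datasets with known truth so every stage has a
    recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
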