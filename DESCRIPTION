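Package: shellmap
Title: RAD-Seq Linkage Mapping of the Land Snail Shell-Polymorphism Supergene
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for discovering anonymous restriction site-associated DNA
    (RAD) markers linked to the Cepaea nemoralis shell colour and banding
    supergene, and for building a local genetic map around it. Covers cross
    genetics under dominance (genotype inference from shell phenotypes,
    Mendelian chi-square tests, a posterior upper bound on the colour-banding
    recombination fraction, and the chromosomal co-location probability of the
    supergene loci), de novo RAD locus construction from barcoded paired-end
    reads (demultiplexing, within-individual allele clustering, PCR-duplicate
    collapse into fragment counts, cross-individual merging and filtering),
    a dropout-tolerant cosegregation search for supergene-linked markers,
    two-point linkage analysis with LOD-based grouping, maximum-likelihood
    marker ordering and Kosambi-scaled map construction, and a synthetic-data
    generator that emulates the full study design from gametes down to reads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
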