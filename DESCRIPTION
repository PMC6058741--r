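Package: ervscan
Title: Discovery, Classification and Expression Profiling of Endogenous
    Retrovirus Protease Loci
Version: 0.9.0
Authors@R:
    person("ERV", "Tools Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for locating endogenous retrovirus (ERV)
    protease (PR) and reverse transcriptase (RT) coding regions in genome
    sequences by six-frame translated homology search and profile scanning,
    detecting LTR retroelements as similar direct-repeat pairs, curating and
    grouping annotations into loci, classifying loci into ERV clades by
    evolutionary placement onto a reference phylogeny, triaging protease
    active-site (B1) and helix (C2) motifs into predicted activity classes,
    and contrasting locus-level FPKM expression between disease conditions
    with nonparametric tests.  Includes a fully seeded synthetic-data
    generator (planted proviruses, clade-structured reference libraries,
    simulated read sets) so that every stage is testable without external
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
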