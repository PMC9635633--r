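Package: haplokit
Title: Census, Polymorphism and Duplication-Block Analysis of Repeat-Dense
    MHC-Like Haplotypes
Version: 0.1.0
Authors@R:
    person("Haplokit", "Developers", email = "haplokit@example.org",
           role = c("aut", "cre"))
Description: Tools for the computational dissection of repeat-dense,
    multigene-family MHC-like haplotypes such as the chicken MHCY region.
    Provides a locus census with pseudogene accounting and gene-density
    arithmetic, RepeatMasker-style repeat-content summaries, Wu-Kabat
    variability-index profiling of class I alignments, an in-silico
    restriction digest with probe hybridization and Southern band matching,
    k-mer anchored dot plots with segmental duplication block calling,
    Nei-Gojobori (1986) dN/dS estimation over structural segments with
    neighbor-joining allele grouping, and a deterministic synthetic
    haplotype generator that emits ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
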