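Package: mtclade
Title: Somatic Mitochondrial DNA Analysis for Clonally Transmissible Cancers
Version: 0.1.0
Authors@R:
    person("mtclade", "developers", email = "mtclade@example.org", role = c("aut", "cre"))
Description: Analysis of somatic mitochondrial DNA variation in clonally
    transmissible cancers sequenced together with their transient hosts.
    Implements substitution and indel post-processing filters under host
    contamination, germline/somatic classification with tumour mtDNA
    fraction estimation and VAF normalisation, a strand-aware 96-class
    trinucleotide mutation spectrum with triplet-frequency normalisation,
    negative-selection inference (VAF distribution tests and a
    context-dependent Poisson dN/dS with likelihood-ratio tests),
    molecular-clock dating of mtDNA capture events, mtDNA copy-number
    estimation from sequencing coverage, qPCR standard-curve arithmetic,
    and a hierarchical haplotype nomenclature. A synthetic-data generator
    emulates tumour clades founded from distinct donor haplotypes so that
    every stage is testable without access to sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
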