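Package: smalr
Title: Single-Molecule Detection and Phasing of Bacterial DNA Methylation
    from SMRT Sequencing Kinetics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects N6-methyladenine and N4-methylcytosine methylation on
    individual bacterial DNA molecules from single-molecule real-time (SMRT)
    sequencing inter-pulse durations (IPDs). Implements single-molecule,
    single-nucleotide (SM_SN) scores against a whole-genome-amplified (WGA)
    kinetic control, their molecule-aggregated analogue (Agg_SN), and pooled
    per-molecule (SM_P) scores for epigenetic phasing of long reads; a
    two-component Gaussian mixture fit by expectation-maximisation for
    estimating the methylated fraction of a motif; IPD-shuffled and WGA
    negative controls with empirical false-discovery-rate calling of
    methylated and non-methylated molecules; in-silico mixing and coverage
    downsampling experiments; and a seeded synthetic kinetics generator with
    molecule/subread structure, sequence-context IPD bias, alignment errors
    and configurable methylation regimes (constitutive, phase-variable,
    stochastic) so the whole method is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    Rsamtools,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
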