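Package: planmosaic
Title: Intraindividual Clone-Sequence Diversity and the Mosaic Meselson Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of intraindividual genetic mosaicism from cloned PCR
    amplicon sequences, as used to study fissiparous, facultative and sexual
    planarian populations. Provides a polymerase-fidelity expectation model
    with singleton recoding of putative PCR artifacts, haplotype collapsing
    and translation under the standard and echinoderm/flatworm mitochondrial
    genetic codes, per-individual diversity and selection statistics
    (haplotype diversity, nucleotide diversity, Nei-Gojobori Ka/Ks),
    between-strategy statistical comparisons, three-level analysis of
    molecular variance with permutation tests, median-joining haplotype
    networks with a star-like/divergent pattern classifier, and a
    forward-time agent-based simulator of somatic mutation accumulation in
    planarian stem-cell pools under homeostasis, fission/regeneration and
    facultative sex (the "mosaic Meselson effect") that emits synthetic
    clone datasets for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
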