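Package: erfsurvey
Title: Genome-Wide Survey and Classification of AP2/ERF Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully reproducible pipeline for genome-wide surveys
    of the AP2/ERF transcription factor superfamily: calibrated
    position-specific scoring matrix (PSSM) detection of AP2 and B3 domains,
    architecture-based assignment to the AP2, ERF (DREB/ERF subfamilies), RAV
    and Soloist families and their fifteen groups, identity-threshold
    ortholog/paralog/duplicate calling from global alignments, neighbor-joining
    phylogenies with bootstrap support, conserved-motif block detection,
    chromosome distribution and tandem-cluster mapping, and EST-based tissue
    expression profiling.  A synthetic-data generator with planted ground truth
    drives validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
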