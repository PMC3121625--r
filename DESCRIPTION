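Package: mitoskew
Title: Strand Asymmetry and Translation-System Analysis for Mitochondrial
    Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing strand-specific nucleotide bias in circular
    mitochondrial genomes: AT- and GC-skew statistics and comparative skew
    atlases, circular sliding-window (G+T)/(A+C) ratio profiles with
    replication-origin inference, homopolymer-run censuses, codon-usage and
    amino-acid composition analysis, anticodon-versatility classification of
    the 22-tRNA metazoan decoding system, and conservation-based genetic-code
    assignment from reference protein alignments.  A seeded synthetic-genome
    generator with planted strand bias, origin-centred gradients and codon
    reassignments makes every stage testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
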