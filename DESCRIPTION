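Package: ssratlas
Title: Gene-Centered Microsatellite Atlas Construction from Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects perfect maximal microsatellites (simple sequence
    repeats, SSRs) in genome assemblies, groups motifs into canonical
    classes under circular permutation and reverse complement, classifies
    repeats by genomic context (exonic, exon-intron junction, intronic,
    intergenic) from a GFF3 annotation, assigns linkage groups, designs
    stringently filtered PCR primer pairs from repeat-masked flanking
    sequence, nominates candidate-gene markers from filtered protein
    alignment hit tables, and emits a joined marker atlas with summary
    tables. Includes a seeded synthetic-genome generator with planted
    repeats and truth tables so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
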