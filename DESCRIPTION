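Package: regscreen
Title: Stringent Comparative Screening for Dimeric Transcription-Factor
    Response Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A comparative-genomics screen for SOX10-type transcription-factor
    response elements. Scans genome sequence for monomeric and head-to-head
    dimeric consensus motifs under a configurable motif grammar with bounded
    spacer lengths, extracts maximal exact-identity conserved segments from
    multi-species alignments, prioritizes candidate elements by conservation,
    coding-sequence exclusion, gene proximity and scored chromatin-peak
    support, tests gene lists for category overrepresentation with an exact
    binomial tail, and summarizes spacer length and GC composition. Includes
    seeded generators for synthetic genomes, alignments, gene models, peak
    sets and annotation universes with machine-readable truth records, so the
    whole pipeline is testable end to end without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
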