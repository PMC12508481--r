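Package: trcatlas
Title: Promoter Secondary-Structure Profiling and Transcription-Replication
    Conflict Site Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking sequence-specific DNA-binding factors to
    R-loop-prone promoters and transcription-replication conflict (TRC)
    sites. Implements strand-aware GC-skew and G-quadruplex propensity
    profiling around transcription start sites, GC-matched control TSS
    sampling, signal metaprofiles, replication fork directionality (RFD)
    from stranded Okazaki-fragment counts, TRC-site discovery from
    high-|RFD| regions intersected with R-loop (DRIPc) peaks, and a
    factor-enrichment ratio statistic at TRC sites versus distal
    controls. Includes seeded synthetic-data generators for every input
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
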