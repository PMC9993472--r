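Package: epiloop
Title: Integrative 3D-Epigenomic Analysis of Chromatin Loops, Regulatory
    Elements, CTCF Binding and DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline linking RNAPII- and CTCF-mediated
    chromatin loops, histone-mark chromatin states, promoter strength,
    CpG methylation, expression specificity and non-coding variants to
    explain condition-specific transcription between two cell states.
    Provides loop clustering into interaction domains (RAID/CCD),
    enhancer-promoter network construction with enhancer-count effects,
    A/B compartment calling, differential CTCF binding with
    methylation coupling, differentially methylated cytosine calling,
    LD-expanded SNP enrichment, a rewired-null co-transcription test,
    and a fully synthetic two-state data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
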