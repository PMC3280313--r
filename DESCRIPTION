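Package: medipscape
Title: Downstream Analysis of MeDIP-Seq Methylation Peak Summits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Annotation-driven downstream analysis of MeDIP-Seq methylation
    peak summits: feature-class methylation densities (promoters, exons,
    introns, UTR-exonic regions, repeat classes), CpG-island methylation
    classification with size binning and genomic-location assignment,
    binned and smoothed metaprofiles around transcription start sites, exon
    junctions and CpG-island starts with expression stratification,
    alternative-splicing (intron retention, cassette exon) methylation
    comparisons, and MeDIP quality metrics (qPCR delta-delta-Ct fold
    enrichment, replicate concordance, saturation curves). Includes a
    seeded synthetic-data generator that emits toy genomes, annotation
    tracks, expression and Ct tables with known ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
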