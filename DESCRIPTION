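Package: mbdmr
Title: Replicate-Consensus Methylated-Region Comparison for MBD-Seq Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative DNA-methylation analysis for enrichment-based
    sequencing (MBD-seq) peak sets: replicate-consensus methylated-region
    extraction, classification of regions as differentially (DMR) or commonly
    (CMR) methylated between two cell types, replicate-concordance
    proportions, annotation of regions against a gene model, a two-group
    microarray expression screen with Benjamini-Hochberg correction, and
    pyrosequencing-style CpG methylation summaries. A seeded synthetic-data
    generator produces replicate peak BED sets with a ground-truth region
    catalog, expression matrices with planted differential probes, and
    per-clone methylation tables, so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
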