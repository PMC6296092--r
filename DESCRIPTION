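Package: sprucesnp
Title: High-Confidence SNP Catalog Construction and Validation for
    Exome-Capture Studies
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates catalogs of high-confidence gene SNPs from
    exome-capture sequencing of species with large genomes, such as Norway
    spruce. Implements dual-caller consensus filtering with a configurable
    cascade of per-site quality criteria, contig-to-target pairing with
    identity, e-value and coverage gates, flanking-sequence extraction for
    probe design, a depth-corrected SNP-abundance statistic (beta) with
    length-weighted aggregation to genes, genotyping-array candidate
    selection, array marker QC including heterozygote-excess paralog
    detection, and Fisher's exact enrichment tests (classic and elim) of GO
    terms, gene families and gene flags among the most polymorphic genes.
    A synthetic-data generator with known ground truth emulates every
    intermediate file of such a study so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
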