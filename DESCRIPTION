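Package: cllpanel
Title: Capture-Panel NGS Analysis of Immunogenetic and Genomic Markers in CLL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrated analysis toolkit for capture-based targeted sequencing
    panels in chronic lymphocytic leukemia (CLL). Reconstructs full-length IGH and
    IGL V(D)J gene rearrangements from soft-clipped aligned reads, annotates them
    (germline V/D/J assignment, somatic hypermutation status with the clinical 98
    percent identity cutoff, CDR3 extraction, productivity, stereotyped subset
    assignment, IGLV3-21 position-110 arginine status), calls the four recurrent
    CLL copy-number alterations (del(17p), del(11q), del(13q), trisomy 12) from
    normalized per-target coverage with a uniformity QC gate, and applies
    VAF-tiered somatic variant filtering. Ships a fully seeded capture-read
    simulator (rearranged loci with junction-spanning soft-clipped reads,
    CNA-scaled depths, spiked variants) used as the test bed for every component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    seqinr,
    vcfR,
    withr
Config/testthat/edition: 3
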