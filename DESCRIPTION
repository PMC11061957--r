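Package: nagpipe
Title: Homology-Projected Gene Annotation and Newly Annotated Gene Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for annotating protein-coding genes in avian genome
    assemblies by projecting template CDS models from reference annotations,
    diagnosing loss-of-function mutations (nonsense and ORF-shift) with
    short-read coverage support, classifying genome-mapped assembled
    transcripts into newly annotated protein-coding genes (NAGs) and lncRNAs,
    consolidating NAGs across genomes with identity-based redundancy removal
    and taxonomic triage, computing genomic-context statistics (G/C windows,
    subtelomeric profiles, G-quadruplex frequencies), building
    presence/absence/pseudogenization matrices with two-way hierarchical
    clustering, and quantifying expression presence, tissue specificity and
    RT-qPCR relative abundance. Ships a seeded synthetic-genome simulator
    that plants genes, mutations, coverage tracks, NAGs and hit tables so the
    whole pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
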