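Package: fldsvirome
Title: Segmented RNA Virus Genome Reconstruction from dsRNA-Seq (FLDS) Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for double-stranded RNA sequencing (FLDS:
    fragmented and primer-ligated dsRNA sequencing) viromes. Calls genome
    terminal ends on contigs from read-end pileups, identifies full-length
    viral genome segments, reconstructs multi-segment RNA virus genome sets
    from conserved terminal sequences with GC-content and ORF non-redundancy
    validation, detects RNA-dependent RNA polymerase (RdRp) signature motifs,
    clusters RdRp sequences into OTUs by greedy centroid clustering, assigns
    putative hosts from viral read abundance in companion ssRNA-seq libraries,
    and summarises transition/transversion composition of single-nucleotide
    variants between genome versions. Includes a ground-truthed synthetic-data
    generator emulating FLDS read structure (terminal read-end enrichment,
    viral/rRNA read-class fractions) so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
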