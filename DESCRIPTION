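Package: fosbridge
Title: Fosmid-Bridged, Genetic-Map-Anchored Scaffolding of Long-Read Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds chromosome-scale super-contigs from whole-genome shotgun
    (WGS) contigs by walking an overlap graph in which WGS contigs are nodes
    and locally assembled fosmid contigs are scored bridging edges, guided by
    a genetic linkage map that orders and orients anchored contigs. Detects
    and splits chimeric contigs, emits gap-free super-contig sequences and
    N-gapped pseudomolecules with AGP, and validates assemblies against
    in-silico nicking-site (optical) maps, calling insertion/deletion
    discrepancies and proposing alternative overlap-graph paths through
    flagged regions. Includes genetic-map marker filtering and sliding-window
    bin genotyping, fosmid pool read selection, telomere and tandem-repeat
    array finders, organelle circularization, contig placement QC,
    presence/absence variation calling, and a deterministic synthetic genome
    simulator with ground-truth evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
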