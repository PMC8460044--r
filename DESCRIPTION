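Package: himseek
Type: Package
Title: Detection and Profiling of Bracovirus Circle Integration Sites in Host Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to discover how polydnavirus (bracovirus) circular dsDNA
    segments integrate into the genome of a parasitized caterpillar host.
    Implements chimeric (split) read detection with an internal seed-and-extend
    local aligner, per-circle breakpoint profiling on circular coordinates,
    classification of circles into conservative-broken (HIM-mediated) and
    random-broken classes, discovery of the "8+5" inverted-repeat host
    integration motif and its deleted spacer, host insertion-landscape
    summaries (genic/intergenic preference, fixed-width window counts, flank
    motif scan), and the qPCR-derived integration-index statistic with
    early/mid/late timing classification. A forward simulator of host-virus
    recombination (circles, integration events, paired-end reads) provides
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
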