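Package: tetherscan
Title: Mapping Episome-Chromosome Tethering from Chromosome Conformation Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to map where a nuclear episome (such as the budding yeast
    2-micron plasmid) tethers to host chromosomes, from binned proximity
    ligation (Hi-C / Micro-C) contact matrices. Computes a per-bin normalized
    trans-contact score, calls contact hotspots as thresholded local maxima on
    the interpolated profile, assesses hotspot overlap with genomic feature
    groups (subtelomeres, long lowly expressed genes) by permutation, builds
    locus-aggregated profiles, sorted heatmaps and observed/expected pair
    pile-ups, screens binned ChIP-style tracks for enrichment at hotspots, and
    provides plasmid copy-number and partition-stability statistics. A
    synthetic-data generator with known tether sites makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
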