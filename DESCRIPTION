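Package: darkmap
Title: Genome Assembly QC: Dark Regions, Gap-Closure Liftover and Sequence Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality control of genome assemblies and of short-read
    mappability against them. Detects "dark" (low-depth) and "camouflaged"
    (adequately covered but non-uniquely mapped) regions from windowed
    depth and mapping-quality tracks with multi-sample consensus; lifts
    old-assembly gaps onto a new assembly via 1 kb flank placement and
    classifies them as closed, artificial or unresolved; annotates sequence
    landmarks (GC windows, CpG islands, telomere repeat arrays, satellite-rich
    centromere blocks) and computes assembly contiguity statistics; estimates
    copy number from normalised and allelic read depth; applies
    annotation-derived transcript and novel-gene filter rules; and evaluates
    paired-end concordance and per-read mapped-base fractions from cs-tagged
    alignments. A seeded synthetic-genome module generates assemblies, depth
    tracks and alignments with known ground truth so every stage is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
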