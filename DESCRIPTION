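Package: oligorepair
Title: Constraint-Guided Processing and Repair of DNA Data Storage Sequencing Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Read-processing toolkit for DNA data storage experiments.
    Synthesized oligonucleotides obey code-imposed design constraints
    (global and windowed GC content, bounded homopolymer length, forbidden
    motifs, k-mer repeat limits, fixed length), so constraint violations in
    sequencing reads are evidence of errors. The package checks reads
    against a declared constraint set, derives a per-base error metric from
    the located violations, and greedily repairs violating sequences by
    editing the highest-error bases until the constraints hold. Around this
    core it provides mean-quality filtering, barcode demultiplexing, primer
    and barcode trimming, dereplication with abundance annotation, greedy
    centroid clustering by similarity, cluster-level representative
    selection and repair, constraint-based filtering and sorting of read
    sets, a synthetic sequencing-channel simulator with ground-truth edit
    tracking, and a single-process pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
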