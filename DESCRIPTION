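Package: subtelcnv
Title: Subtelomeric Copy-Number Cassette Discovery on Synthetic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-backed pipeline for localizing and characterizing a
    subtelomeric gene-amplification cassette of the kind that drives
    target-site herbicide resistance in weeds. Generates susceptible/resistant
    genome pairs with Arabidopsis-type telomere arrays, divergent subtelomeric
    repeat arrays and a palindromic tandem duplication cassette with
    machine-readable ground truth; maps synthetic reads with a seed-and-extend
    aligner or imports SAM alignments; calls windowed read-depth CNV segments
    and population-consensus duplication events; validates cassette domain
    junctions by spanning-read counting and infers inverted-tandem
    architecture from the coverage-ratio signature; detects telomeric and
    subtelomeric tandem repeat units, counts their orientations and relates
    them by neighbor joining on pairwise identity; and summarizes per-region
    differential-expression significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stringi,
    jsonlite,
    ape,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
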