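Package: seqtracks
Title: Coverage, Mismatch and Variant-Density Tracks with Anomaly Region
    Detection for Partitioned Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genome-browser-ready evidence tracks from whole-genome
    resequencing data aligned to a large, partitioned reference assembly
    (chromosome-scale pseudomolecules split into indexable "parts").  From
    MAPQ-filtered alignments it computes per-base read-depth profiles and
    pileup mismatch fractions; from variant calls it derives quality and
    zygosity classes and windowed variant densities.  Depth and density
    signals are segmented into high/low anomaly regions by a
    threshold-merge-length-filter rule, and regions are jointly typed as
    reference-like, divergent, deleted/introgressed, or copy-number gain.
    Includes the pseudomolecule-to-part coordinate liftover (with GFF3
    splitting and functional-annotation merging) and a seeded synthetic-data
    generator with planted deletions, introgressions, copy-number gains and
    haplotype blocks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    yaml,
    Rsamtools,
    Biostrings,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
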