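Package: genonav
Title: Marker-Oriented Storage, Filtering and Export of Genomic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genotype-exploration engine for population-scale variant data.
    Imports VCF and HapMap files into a marker-oriented, chunk-indexed store
    holding variants, per-run genotypes and functional annotations; evaluates
    real-time filters on variant features (type, sequence, position, allele
    count, SnpEff effect and gene) and on genotype-level criteria (genotype
    patterns, per-sample GQ/DP masking, missing-data ratio, minor allele
    frequency) using a two-step query strategy with chunked execution, count
    caching, progress reporting and abort; and exports filtered selections to
    seven standard population-genetics formats (VCF, Eigenstrat, GFF3, BED,
    HapMap, DARwin, PLINK) with individual-based genotype consolidation and
    preservation of phasing across filtered-out positions.  A deterministic
    synthetic-fixture generator with a machine-readable truth table supports
    fully reproducible testing at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), rtracklayer, BiocGenerics, knitr
Config/testthat/edition: 3
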