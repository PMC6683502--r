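Package: gbscnv
Title: Copy Number Variant Calling from Genotyping-by-Sequencing Read Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects copy number variants (homozygous deletions, hemizygous
    deletions and duplications) in mutant populations from
    genotyping-by-sequencing (GBS) read counts. Reads are tallied into
    fixed-width genomic bins, counts are normalized across samples and
    filtered down to informative bins, per-bin log2 ratios against the
    population mean are segmented with an exact penalized robust (biweight
    loss) changepoint solver, and segments are classified into CNV types with
    support filters and minimum/maximum span estimates. Includes a companion
    homozygous-deletion caller for array comparative genomic hybridization
    (aCGH) probe profiles, benchmarking utilities (event matching,
    size-agreement statistics, gene-overlap counts), droplet digital PCR
    copy-number arithmetic and validation rules, and a synthetic population
    simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
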