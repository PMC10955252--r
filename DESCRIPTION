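Package: smemcache
Title: SMEM Seeding over an FM-Index with Trie-Based Caching of
    Seeding Operations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds a bidirectional (FMD-style) FM-index over a reference
    genome and implements super-maximal exact match (SMEM) seeding as used
    by short-read aligners, together with forward and backward SMEM search
    tries that cache every intermediate suffix-array-interval computation
    within a batch of reads, plus a per-batch memo that merges repeated
    suffix-array lookups. When reads arrive clustered by genomic position
    (the layout produced by reordering-based FASTQ compressors), most
    index queries are answered from the caches instead of the FM-index;
    the package counts real versus cached operations and guarantees that
    cached seeding emits exactly the seeds of uncached seeding. A read
    simulator and reference-free reorderer are included for quantifying
    the savings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp (>= 1.0.0),
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
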