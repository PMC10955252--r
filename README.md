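# smemcache

SMEM seeding over an FMD index, with trie-based caching of every
intermediate seeding operation — and proof that caching never changes the
seeds.

## The problem

Short-read aligners spend a large share of their time in *seeding*:
finding super-maximal exact matches (SMEMs) between each read and the
reference with an FM-index. Two primitives dominate the cost:

- **BWT-extend** — given the suffix-array interval `(k, l, s)` of a
  pattern `P` (where `k` indexes `P`, `l` indexes `revcomp(P)` and `s` is
  the occurrence count over both strands), compute the interval of `bP`
  or `Pb`;
- **SAL** (suffix-array lookup) — resolve one rank of an interval to a
  genome position through a sampled suffix array.

Reordering-based FASTQ compressors (SPRING, PgRC, Minicom, ...) discard
the original read order and cluster reads by inferred genomic position.
Consecutive reads in that layout overlap heavily, so consecutive seeding
jobs repeat each other's index operations. `smemcache` caches all
intermediate suffix-array intervals of a batch of reads in two tries —
the forward and backward *SMEM search tries* (SST) — and memoises SAL per
batch so matches with identical or overlapping intervals are resolved
once. Every cache is transparent: seeding with caches emits byte-for-byte
the seeds of uncached seeding, while operation counters record how many
BWT-extend and SAL requests actually had to touch the index.

The package is aimed at people studying alignment/compression interplay:
it provides the FMD index, the two-stage SMEM search (`SuperMEM1` sweep
with `min-intv = 1`, plus re-seeding of long SMEMs at their middle base),
the caches, a read simulator with a compressor-style reorderer, and
experiment drivers that quantify the savings as functions of coverage and
of the re-seeding factor `-r`.

## A worked example

```r
library(smemcache)

cfg    <- sim_config(genome_length = 20000, coverage = 10, seed = 42)
genome <- simulate_genome(cfg)
idx    <- fmd_index(c(sim = genome))
reads  <- reorder_reads(simulate_reads(genome, cfg), "oracle")

cached <- run_seeding(idx, reads, cache = TRUE)
plain  <- run_seeding(idx, reads, cache = FALSE, sal_merge = FALSE)

identical(cached$seeds, plain$seeds)
#> [1] TRUE
head(cached$seeds, 5)
#>     read_id qbeg qend strand rbeg intv_size origin
#> 1 sim000982    0   35      +    3         1   smem
#> 2 sim000982   36  100      +   39         1   smem
#> 3 sim001750    0   68      +    4         1   smem
#> 4 sim001750   69  100      +   73         1   smem
#> 5 sim000912    0  100      +    6         1   smem
op_reduction(cached$stats, plain$stats)
#> [1] 30.37808
```

Read `sim000982` carries a substitution around offset 35, so it splits
into two flanking SMEMs; `sim000912` is error-free and yields one
whole-read seed. The caches answered 30.4% of this small run's real
index operations; the saving grows with coverage (see
`experiment_coverage()`) because deeper position-sorted data repeats
itself more.

Each seed row is an exact match: `qbeg`/`qend` are 0-based half-open read
offsets, `rbeg` the leftmost forward-strand reference position,
`intv_size` the match's occurrence count, and `origin` whether it came
from the primary sweep or from re-seeding.

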