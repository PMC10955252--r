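#' Run seeding over a read set and collect operation statistics
#'
#' Convenience driver: creates a fresh seeder, seeds all reads, and
#' returns the seeds together with per-run totals and per-read averages
#' of real versus requested FM-index operations.
#'
#' @param index An [fmd_index()].
#' @param reads Character vector of reads, or a data frame with `id` and
#'   `read` columns.
#' @param params A [seeding_params()].
#' @param cache,sal_merge Passed to [smem_seeder()].
#' @return A list with elements `seeds` (data frame) and `stats` (list).
#' @export
run_seeding <- function(index, reads, params = seeding_params(),
                        cache = TRUE, sal_merge = cache) {
  if (is.data.frame(reads)) {
    ids <- reads$id
    reads <- reads$read
  } else {
    ids <- NULL
  }
  sd <- smem_seeder(index, params, cache = cache, sal_merge = sal_merge)
  seeds <- seed_reads(sd, reads, ids = ids)
  list(seeds = seeds, stats = seeding_stats(sd))
}

#' Assemble the statistics report of a seeder
#'
#' @param seeder An `smem_seeder`.
#' @return A list with `params`, `cache`, `sal_merge`, `totals` and
#'   `per_read` components (the shape written by [write_stats_json()]).
#' @export
seeding_stats <- function(seeder) {
  cnt <- seeder_counters(seeder)
  nr <- max(cnt$reads_done, 1)
  list(params = unclass(seeder$params), cache = seeder$cache,
       sal_merge = seeder$sal_merge,
       totals = cnt[c("bwt_queries", "bwt_real", "sal_queries", "sal_real")],
       reads = cnt$reads_done, batches_reset = cnt$batches_reset,
       per_read = list(bwt_queries = cnt$bwt_queries / nr,
                       bwt_real = cnt$bwt_real / nr,
                       sal_queries = cnt$sal_queries / nr,
                       sal_real = cnt$sal_real / nr))
}

#' @rdname seeding_stats
#' @param stats A stats list from [seeding_stats()] or [run_seeding()].
#' @param path Output path for the JSON report.
#' @return `write_stats_json` returns `path` invisibly.
#' @export
write_stats_json <- function(stats, path) {
  jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Percentage reduction in real FM-index operations
#'
#' `100 * (1 - real(cached) / real(uncached))` where real operations are
#' BWT-extends plus SAL walks that actually touched the index.
#'
#' @param stats_cached,stats_uncached Stats lists from [run_seeding()].
#' @return A single percentage.
#' @export
op_reduction <- function(stats_cached, stats_uncached) {
  on <- stats_cached$totals$bwt_real + stats_cached$totals$sal_real
  off <- stats_uncached$totals$bwt_real + stats_uncached$totals$sal_real
  100 * (1 - on / off)
}

#' Coverage sweep: operation savings versus sequencing depth
#'
#' For each coverage, simulates reads over one fixed genome, reorders
#' them by true position (oracle mode), and runs seeding with and without
#' caching. As coverage grows, reordered neighbouring reads overlap more,
#' so the per-read number of real FM-index operations with caching
#' decreases while the uncached cost stays flat.
#'
#' @param cfg A [sim_config()]; its `coverage` field is overridden by
#'   `coverages`. The genome is simulated once from `cfg$seed`; each
#'   coverage draws reads with seed `cfg$seed + coverage`.
#' @param coverages Numeric vector of fold coverages.
#' @param params A [seeding_params()].
#' @return A data frame with one row per coverage: per-read real and
#'   requested operation counts for the cached and uncached runs, and the
#'   percentage reduction in real operations.
#' @export
experiment_coverage <- function(cfg = sim_config(),
                                coverages = c(5, 10, 20, 40),
                                params = seeding_params()) {
  genome <- simulate_genome(cfg)
  idx <- fmd_index(c(sim = genome))
  rows <- lapply(coverages, function(cov) {
    ccfg <- cfg
    ccfg$coverage <- cov
    ccfg$seed <- cfg$seed + as.integer(cov)
    reads <- reorder_reads(simulate_reads(genome, ccfg), "oracle")
    on <- run_seeding(idx, reads, params, cache = TRUE, sal_merge = TRUE)
    off <- run_seeding(idx, reads, params, cache = FALSE, sal_merge = FALSE)
    data.frame(coverage = cov, n_reads = nrow(reads),
               bwt_real_per_read_cached = on$stats$per_read$bwt_real,
               sal_real_per_read_cached = on$stats$per_read$sal_real,
               bwt_real_per_read_uncached = off$stats$per_read$bwt_real,
               sal_real_per_read_uncached = off$stats$per_read$sal_real,
               reduction_pct = op_reduction(on$stats, off$stats))
  })
  do.call(rbind, rows)
}

#' Re-seeding sweep: cache robustness to the -r parameter
#'
#' Lowering the re-seeding factor `r` relaxes the trigger and generates
#' many more seeding operations. Uncached seeding pays for every one of
#' them; cached seeding answers most of the extra, highly repetitive
#' queries from the tries, so its real-access count grows by a much
#' smaller factor.
#'
#' @param cfg A [sim_config()].
#' @param r_values Re-seeding factors to sweep (descending by convention).
#' @param params Base [seeding_params()]; `reseed_r` is overridden.
#' @return A data frame with one row per `r`: total queries, real
#'   accesses for cached/uncached runs.
#' @export
experiment_reseed <- function(cfg = sim_config(), r_values = c(1.5, 1.3, 1.1),
                              params = seeding_params()) {
  genome <- simulate_genome(cfg)
  idx <- fmd_index(c(sim = genome))
  reads <- reorder_reads(simulate_reads(genome, cfg), "oracle")
  rows <- lapply(r_values, function(r) {
    p <- params
    p$reseed_r <- r
    on <- run_seeding(idx, reads, p, cache = TRUE, sal_merge = TRUE)
    off <- run_seeding(idx, reads, p, cache = FALSE, sal_merge = FALSE)
    data.frame(r = r, n_reads = nrow(reads),
               queries = off$stats$totals$bwt_queries +
                 off$stats$totals$sal_queries,
               real_cached = on$stats$totals$bwt_real +
                 on$stats$totals$sal_real,
               real_uncached = off$stats$totals$bwt_real +
                 off$stats$totals$sal_real,
               reduction_pct = op_reduction(on$stats, off$stats))
  })
  do.call(rbind, rows)
}

#' Operation-savings analogue of the headline redundancy measurement
#'
#' Simulates a genome and oracle-reordered reads under `cfg`, seeds them
#' with and without the caches, and reports the percentage reduction in
#' real FM-index operations alongside both runs' statistics.
#'
#' @param cfg A [sim_config()].
#' @param params A [seeding_params()].
#' @return A list with `reduction_pct`, `stats_cached`, `stats_uncached`,
#'   `n_reads`.
#' @export
measure_redundancy <- function(cfg = sim_config(),
                               params = seeding_params()) {
  genome <- simulate_genome(cfg)
  idx <- fmd_index(c(sim = genome))
  reads <- reorder_reads(simulate_reads(genome, cfg), "oracle")
  on <- run_seeding(idx, reads, params, cache = TRUE, sal_merge = TRUE)
  off <- run_seeding(idx, reads, params, cache = FALSE, sal_merge = FALSE)
  list(reduction_pct = op_reduction(on$stats, off$stats),
       stats_cached = on$stats, stats_uncached = off$stats,
       n_reads = nrow(reads))
}
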