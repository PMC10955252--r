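#' Seeding parameters
#'
#' Defaults follow common short-read aligner practice: the initial
#' SAI-size threshold `min_intv` is 1 (every occurring match is kept),
#' seeds shorter than `min_seed_len = 19` are discarded, re-seeding is
#' triggered for SMEMs longer than `min_seed_len * reseed_r` with
#' `reseed_r = 1.5`, matches occurring more than `max_occ = 500` times are
#' not materialised, and the caches are cleared every `batch_size = 512`
#' reads.
#'
#' @param min_intv Initial SAI-size threshold for SMEM collection.
#' @param min_seed_len Minimum seed length (bases).
#' @param reseed_r Re-seeding trigger factor (> 1).
#' @param max_occ Per-match cap on suffix-array lookups.
#' @param batch_size Reads sharing one cache before reset.
#' @return A list of class `seeding_params`.
#' @export
seeding_params <- function(min_intv = 1L, min_seed_len = 19L, reseed_r = 1.5,
                           max_occ = 500, batch_size = 512L) {
  stopifnot(min_intv >= 1, min_seed_len >= 1, reseed_r > 1, max_occ >= 1,
            batch_size >= 1)
  structure(list(min_intv = as.integer(min_intv),
                 min_seed_len = as.integer(min_seed_len),
                 reseed_r = as.numeric(reseed_r),
                 max_occ = as.numeric(max_occ),
                 batch_size = as.integer(batch_size)),
            class = "seeding_params")
}

#' Create a seeder
#'
#' A seeder bundles an FMD index with seeding parameters, operation
#' counters and (optionally) the forward/backward SMEM search tries and
#' the per-batch SAL memo. With `cache = TRUE` every BWT-extend request
#' first consults the tries and only touches the FM-index on a miss; with
#' `sal_merge = TRUE` repeated suffix-array lookups of the same rank
#' within a batch are answered from a memo, which merges the lookups of
#' exact matches with identical or overlapping intervals. Caching is
#' transparent: the emitted seeds are identical with and without it.
#'
#' @param index An [fmd_index()].
#' @param params A [seeding_params()].
#' @param cache Use the SMEM search tries for BWT-extend.
#' @param sal_merge Memoise suffix-array lookups per batch.
#' @return An object of class `smem_seeder`.
#' @export
smem_seeder <- function(index, params = seeding_params(), cache = TRUE,
                        sal_merge = cache) {
  stopifnot(inherits(index, "fmd_index"), inherits(params, "seeding_params"))
  ptr <- seeder_new_cpp(index$ptr, unclass(params), isTRUE(cache),
                        isTRUE(sal_merge))
  structure(list(ptr = ptr, index = index, params = params,
                 cache = isTRUE(cache), sal_merge = isTRUE(sal_merge)),
            class = "smem_seeder")
}

#' @export
print.smem_seeder <- function(x, ...) {
  cat("SMEM seeder (cache", if (x$cache) "on," else "off,",
      "SAL merge", if (x$sal_merge) "on)" else "off)", "\n")
  p <- x$params
  cat("  min_intv", p$min_intv, "| min_seed_len", p$min_seed_len,
      "| reseed_r", p$reseed_r, "| max_occ", p$max_occ,
      "| batch_size", p$batch_size, "\n")
  cnt <- seeder_counters(x)
  cat("  reads processed:", cnt$reads_done, "\n")
  invisible(x)
}

#' Operation counters of a seeder
#'
#' `*_queries` counts every BWT-extend / SAL request issued by the seeding
#' algorithm; `*_real` counts the subset that actually touched the
#' FM-index. Cache hits are `queries - real`.
#'
#' @param seeder An `smem_seeder`.
#' @return A list with `bwt_queries`, `bwt_real`, `sal_queries`,
#'   `sal_real`, `reads_done`, `batches_reset`.
#' @export
seeder_counters <- function(seeder) {
  seeder_counters_cpp(seeder$ptr)
}

#' All SMEMs covering one read position
#'
#' The forward stage extends exact matches rightwards from the pivot base,
#' recording a match whenever the interval size changes and stopping when
#' it drops below `min_intv` or the read ends. The backward stage extends
#' the retained matches leftwards to their limit; matches contained in a
#' longer surviving match are dropped. All extensions go through the
#' seeder's accessor, so the caches interpose when enabled.
#'
#' @param seeder An `smem_seeder`.
#' @param read A read string over ACGT.
#' @param pivot 0-based read position every returned SMEM must cover.
#' @param min_intv SAI-size threshold (defaults to the seeder's).
#' @return A data frame with columns `qbeg`, `qend` (0-based, half-open),
#'   `k`, `l`, `s` (the bi-interval) and `origin`.
#' @export
super_mem1 <- function(seeder, read, pivot, min_intv = NULL) {
  min_intv <- min_intv %||% seeder$params$min_intv
  seeder_supermem1_cpp(seeder$ptr, toupper(read), as.integer(pivot),
                       as.numeric(min_intv))
}

#' Collect the SMEMs of a whole read
#'
#' Sweeps the read with the initial `min_intv`, choosing the next pivot
#' one past the right end of the longest SMEM of each round, then
#' re-seeds every SMEM longer than `min_seed_len * reseed_r` at its middle
#' base with `min_intv` raised to the SMEM's occurrence count plus one.
#' The result is deduplicated and filtered to `min_seed_len`. Reads are
#' split at `N`; each segment is seeded independently with offsets
#' restored.
#'
#' @inheritParams super_mem1
#' @return A data frame as in [super_mem1()]; `origin` is `"smem"` or
#'   `"reseed"`.
#' @export
collect_smems <- function(seeder, read) {
  seeder_collect_cpp(seeder$ptr, toupper(read))
}

#' Seed a set of reads
#'
#' Runs the full per-read pipeline (SMEM sweep, re-seeding, seed
#' materialisation through SAL) over `reads` in order, maintaining the
#' caches across reads and resetting them every `batch_size` reads.
#' Matches occurring more than `max_occ` times are skipped entirely.
#'
#' @param seeder An `smem_seeder`.
#' @param reads Character vector of reads (ACGTN). Reads containing other
#'   characters are skipped with a warning.
#' @param ids Read identifiers (default `names(reads)` or `read1`, ...).
#' @return A data frame of seeds with columns `read_id`, `qbeg`, `qend`,
#'   `strand`, `rbeg`, `intv_size`, `origin`, ordered by read then
#'   `(qbeg, rbeg)`. Coordinates are 0-based; `rbeg` is the leftmost
#'   forward-strand reference position.
#' @export
seed_reads <- function(seeder, reads, ids = NULL) {
  nm <- names(reads)
  reads <- toupper(as.character(reads))
  if (is.null(ids)) ids <- nm %||% paste0("read", seq_along(reads))
  bad <- grepl("[^ACGTN]", reads)
  if (any(bad)) {
    warning(sum(bad), " read(s) with characters outside A/C/G/T/N skipped: ",
            paste(utils::head(ids[bad], 3), collapse = ", "),
            if (sum(bad) > 3) ", ..." else "", call. = FALSE)
    reads <- reads[!bad]
    ids <- ids[!bad]
  }
  if (length(reads) == 0) {
    return(data.frame(read_id = character(0), qbeg = integer(0),
                      qend = integer(0), strand = character(0),
                      rbeg = numeric(0), intv_size = numeric(0),
                      origin = character(0), stringsAsFactors = FALSE))
  }
  res <- seeder_run_cpp(seeder$ptr, reads)
  df <- res$seeds
  data.frame(read_id = ids[df$read], qbeg = df$qbeg, qend = df$qend,
             strand = ifelse(df$rev, "-", "+"), rbeg = df$rbeg,
             intv_size = df$intv_size,
             origin = ifelse(df$reseed, "reseed", "smem"),
             stringsAsFactors = FALSE)
}

#' Write seeds as TSV
#'
#' Deterministic tab-separated output with columns `read_id`, `qbeg`,
#' `qend`, `strand`, `rbeg`, `interval_size`, `origin`.
#'
#' @param seeds A data frame from [seed_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seeds_tsv <- function(seeds, path) {
  out <- data.frame(read_id = seeds$read_id, qbeg = seeds$qbeg,
                    qend = seeds$qend, strand = seeds$strand,
                    rbeg = format(seeds$rbeg, scientific = FALSE, trim = TRUE),
                    interval_size = format(seeds$intv_size,
                                           scientific = FALSE, trim = TRUE),
                    origin = seeds$origin, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Check seed validity against the reference
#'
#' Every seed must satisfy the exact-match guarantee: the read substring
#' equals the reference substring at `(rbeg, len)` on the `+` strand, or
#' its reverse complement on the `-` strand.
#'
#' @param index The `fmd_index` the seeds were produced with.
#' @param seeds A data frame from [seed_reads()].
#' @param reads The reads, named (or indexed) by `read_id`.
#' @return Logical vector, one entry per seed.
#' @export
check_seeds <- function(index, seeds, reads) {
  if (nrow(seeds) == 0) return(logical(0))
  nm <- names(reads)
  reads <- toupper(as.character(reads))
  names(reads) <- nm %||% paste0("read", seq_along(reads))
  rd <- reads[seeds$read_id]
  qsub <- substring(rd, seeds$qbeg + 1, seeds$qend)
  len <- seeds$qend - seeds$qbeg
  rsub <- substring(index$seq, seeds$rbeg + 1, seeds$rbeg + len)
  minus <- seeds$strand == "-"
  if (any(minus)) rsub[minus] <- revcomp(rsub[minus])
  qsub == rsub
}
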