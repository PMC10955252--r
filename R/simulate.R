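#' Simulation configuration
#'
#' Defaults describe the study conditions used throughout the package:
#' a 100 kb uniform-random genome, 100 bp reads at 30-fold coverage with
#' 0.5% substitution errors, half the reads reverse-complemented.
#'
#' @param genome_length Genome length (bases).
#' @param repeat_count,repeat_length Planted duplicate segments: number of
#'   extra copies and their length (0 disables planting).
#' @param read_length Read length (bases).
#' @param coverage Fold coverage (> 0).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param revcomp_fraction Probability a read is reverse-complemented.
#' @param seed RNG seed (integer).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000, repeat_count = 0,
                       repeat_length = 0, read_length = 100, coverage = 30,
                       error_rate = 0.005, revcomp_fraction = 0.5, seed = 1L) {
  stopifnot(genome_length >= 1, coverage > 0, error_rate >= 0, error_rate < 1,
            read_length >= 1, read_length <= genome_length,
            revcomp_fraction >= 0, revcomp_fraction <= 1)
  if (repeat_count > 0 && repeat_length > genome_length) {
    stop("repeat_length cannot exceed genome_length", call. = FALSE)
  }
  structure(list(genome_length = genome_length, repeat_count = repeat_count,
                 repeat_length = repeat_length, read_length = read_length,
                 coverage = coverage, error_rate = error_rate,
                 revcomp_fraction = revcomp_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a random genome
#'
#' I.i.d. uniform ACGT of the configured length; afterwards
#' `repeat_count` copies of a randomly chosen `repeat_length`-bp segment
#' are pasted at random positions, creating the multi-occurrence matches
#' that exercise re-seeding. Deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A single genome string.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  g <- sample(BASES, cfg$genome_length, replace = TRUE)
  if (cfg$repeat_count > 0 && cfg$repeat_length > 0) {
    L <- cfg$genome_length
    rl <- cfg$repeat_length
    src <- sample.int(L - rl + 1, 1)
    unit <- g[src:(src + rl - 1)]
    for (i in seq_len(cfg$repeat_count)) {
      at <- sample.int(L - rl + 1, 1)
      g[at:(at + rl - 1)] <- unit
    }
  }
  paste(g, collapse = "")
}

#' Simulate uniform-coverage reads
#'
#' Draws `round(coverage * genome_length / read_length)` reads at uniform
#' start positions, applies i.i.d. substitution errors at `error_rate`,
#' and reverse-complements each read with probability `revcomp_fraction`.
#' The true position and strand are recorded. Uses the RNG stream seeded
#' with `cfg$seed + 1` so the genome and the reads are independently
#' reproducible.
#'
#' @param genome A genome string (e.g. from [simulate_genome()]).
#' @param cfg A [sim_config()].
#' @return A data frame with columns `id`, `read`, `true_pos` (0-based)
#'   and `true_strand`.
#' @export
simulate_reads <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  L <- nchar(genome)
  rl <- cfg$read_length
  n <- round(cfg$coverage * L / rl)
  pos <- sample.int(L - rl + 1, n, replace = TRUE) - 1
  reads <- substring(genome, pos + 1, pos + rl)
  # substitution errors: always shift to a *different* base
  nerr_total <- 0
  err <- which(runif(n * rl) < cfg$error_rate)
  if (length(err) > 0) {
    ri <- (err - 1) %/% rl + 1
    off <- (err - 1) %% rl + 1
    orig <- substring(reads[ri], off, off)
    shift <- sample.int(3, length(err), replace = TRUE)
    newb <- BASES[(match(orig, BASES) - 1 + shift) %% 4 + 1]
    for (j in seq_along(err)) {
      substring(reads[ri[j]], off[j], off[j]) <- newb[j]
    }
    nerr_total <- length(err)
  }
  strand <- ifelse(runif(n) < cfg$revcomp_fraction, "-", "+")
  if (any(strand == "-")) {
    reads[strand == "-"] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[strand == "-"])))
  }
  data.frame(id = sprintf("sim%06d", seq_len(n)), read = reads,
             true_pos = pos, true_strand = strand, stringsAsFactors = FALSE)
}

#' Reorder reads the way reordering-based compressors lay them out
#'
#' Reordering-based FASTQ compressors cluster similar reads by their
#' inferred genomic positions, so consecutive reads share large overlaps.
#' Three modes are provided: `"oracle"` strand-normalises the reads to the
#' forward strand and sorts them by true position (the idealised
#' compressor layout; requires simulation truth); `"minimizer"` is
#' reference-free and buckets reads by their canonical smallest k-mer
#' (k = 12) over both strands, orders buckets lexicographically and,
#' within a bucket, by minimizer offset descending so overlapping reads
#' stack; `"none"` is a pass-through (the plain FASTQ baseline).
#'
#' @param reads A data frame from [simulate_reads()], or any data frame
#'   with a `read` column (plus `true_pos`/`true_strand` for oracle mode).
#' @param mode `"oracle"`, `"minimizer"` or `"none"`.
#' @param k Minimizer k-mer length (minimizer mode).
#' @return The reordered data frame.
#' @export
reorder_reads <- function(reads, mode = c("oracle", "minimizer", "none"),
                          k = 12L) {
  mode <- match.arg(mode)
  if (is.character(reads)) {
    reads <- data.frame(id = paste0("read", seq_along(reads)), read = reads,
                        stringsAsFactors = FALSE)
  }
  if (mode == "none") return(reads)
  if (mode == "oracle") {
    if (is.null(reads$true_pos) || is.null(reads$true_strand)) {
      stop("oracle reordering requires true_pos/true_strand columns",
           call. = FALSE)
    }
    out <- reads
    minus <- out$true_strand == "-"
    if (any(minus)) {
      out$read[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(out$read[minus])))
      out$true_strand[minus] <- "+"
    }
    return(out[order(out$true_pos, seq_len(nrow(out))), , drop = FALSE])
  }
  # minimizer mode
  mins <- t(vapply(reads$read, canonical_minimizer, c("", ""), k = k,
                   USE.NAMES = FALSE))
  ord <- order(mins[, 1], -as.integer(mins[, 2]), seq_len(nrow(reads)))
  reads[ord, , drop = FALSE]
}

canonical_minimizer <- function(read, k) {
  L <- nchar(read)
  if (L < k) return(c(read, "1"))
  km <- substring(read, 1:(L - k + 1), k:L)
  rc <- revcomp(read)
  kmr <- substring(rc, 1:(L - k + 1), k:L)
  all <- c(km, kmr)
  best <- which(all == min(all))[1]
  c(all[best], as.character((best - 1L) %% (L - k + 1L) + 1L))
}

#' Write reads as FASTQ / read reads from FASTQ or FASTA
#'
#' The FASTQ writer emits constant quality `"I"`. The reader accepts
#' FASTQ or FASTA (autodetected by extension, override with `format`).
#'
#' @param reads Data frame with `id` and `read` columns, or a character
#'   vector.
#' @param path File path.
#' @param format `"auto"`, `"fastq"` or `"fasta"`.
#' @return `write_fastq` returns `path` invisibly; `read_reads` returns a
#'   data frame with `id` and `read`.
#' @export
write_fastq <- function(reads, path) {
  if (is.character(reads)) {
    reads <- data.frame(id = names(reads) %||% paste0("read", seq_along(reads)),
                        read = unname(reads), stringsAsFactors = FALSE)
  }
  qual <- strrep("I", nchar(reads$read))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$read, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_reads <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
      "fastq"
    } else {
      "fasta"
    }
  }
  dss <- Biostrings::readDNAStringSet(path, format = format)
  ids <- sub("\\s.*$", "", names(dss))
  data.frame(id = ids, read = toupper(as.character(dss)),
             stringsAsFactors = FALSE)
}

#' Write simulation truth as TSV
#'
#' @param reads Data frame from [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(reads, path) {
  write.table(reads[, c("id", "true_pos", "true_strand")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
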