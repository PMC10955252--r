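#' Build a bidirectional (FMD-style) FM-index
#'
#' Indexes a reference genome together with its reverse complement so that
#' exact matches can be extended one base at a time in either direction
#' (BWT-extend) and located by sampled suffix-array lookup (SAL). Runs of
#' `N` are excluded from the index: the reference is segmented at `N`s and
#' each segment is indexed with its original coordinate recorded, so no
#' match ever spans an ambiguous base. Multi-record FASTA input is
#' concatenated with per-record offsets recorded; all coordinates reported
#' by the package are 0-based positions in that concatenation.
#'
#' @param x A reference: path to a FASTA file, a named character vector of
#'   sequences, or a [Biostrings::DNAStringSet].
#' @param sa_sample_interval Suffix-array sampling interval `d` (text
#'   positions). Every rank lookup LF-steps to the nearest sampled position,
#'   so smaller values trade memory for fewer steps per SAL. Default 32.
#' @return An object of class `fmd_index`.
#' @examples
#' idx <- fmd_index(c(chr = "ACGTACGTACGTACGT"), sa_sample_interval = 4)
#' idx
#' @export
fmd_index <- function(x, sa_sample_interval = 32L) {
  seqs <- load_reference(x)
  offsets <- c(0, cumsum(nchar(seqs)))[seq_along(seqs)]
  records <- data.frame(name = names(seqs), offset = offsets,
                        length = nchar(seqs), stringsAsFactors = FALSE)

  segs <- character(0)
  seg_starts <- numeric(0)
  for (i in seq_along(seqs)) {
    sp <- split_at_n(seqs[[i]])
    segs <- c(segs, sp$seq)
    seg_starts <- c(seg_starts, sp$start + offsets[i])
  }
  if (length(segs) == 0) {
    stop("reference contains no indexable (non-N) bases", call. = FALSE)
  }
  ref_len <- sum(nchar(seqs))
  ptr <- fmd_build_cpp(segs, seg_starts, ref_len, as.integer(sa_sample_interval))
  structure(
    list(ptr = ptr, records = records, seq = paste(seqs, collapse = ""),
         sa_sample_interval = as.integer(sa_sample_interval)),
    class = "fmd_index")
}

load_reference <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    seqs <- toupper(as.character(x))
  } else if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
             file.exists(x)) {
    dss <- Biostrings::readDNAStringSet(x)
    seqs <- toupper(as.character(dss))
  } else if (is.character(x)) {
    seqs <- toupper(x)
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  } else {
    stop("reference must be a FASTA path, character vector or DNAStringSet",
         call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("reference records with characters outside A/C/G/T/N: ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  }
  if (any(nchar(seqs) == 0)) stop("empty reference record", call. = FALSE)
  seqs
}

# split one sequence into N-free segments with 0-based start offsets
split_at_n <- function(seq) {
  m <- gregexpr("[ACGT]+", seq)[[1]]
  if (m[1] == -1) return(list(seq = character(0), start = numeric(0)))
  list(seq = substring(seq, m, m + attr(m, "match.length") - 1),
       start = as.numeric(m) - 1)
}

#' @export
print.fmd_index <- function(x, ...) {
  info <- fmd_info_cpp(x$ptr)
  cat("FMD index:", info$n_segments, "segment(s) over",
      nrow(x$records), "record(s),", format(info$ref_len, big.mark = ","),
      "bp reference\n")
  cat("  text length:", format(info$n, big.mark = ","),
      "| SA sampling interval:", info$sa_interval, "\n")
  invisible(x)
}

#' Construct a bidirectional suffix-array interval
#'
#' @param k Suffix-array start rank of the pattern.
#' @param l Suffix-array start rank of the pattern's reverse complement.
#' @param s Interval size (occurrence count over both strands).
#' @return A named numeric vector of class `bi_interval`.
#' @export
bi_interval <- function(k, l, s) {
  structure(c(k = as.numeric(k), l = as.numeric(l), s = as.numeric(s)),
            class = "bi_interval")
}

#' Interval of the empty pattern (the whole suffix-array range)
#' @param index An `fmd_index`.
#' @return A `bi_interval`.
#' @export
empty_interval <- function(index) {
  iv <- fmd_whole_cpp(index$ptr)
  bi_interval(iv[["k"]], iv[["l"]], iv[["s"]])
}

#' Interval of a single base
#' @param index An `fmd_index`.
#' @param base One of "A", "C", "G", "T".
#' @return A `bi_interval`.
#' @export
base_interval <- function(index, base) {
  iv <- fmd_base_interval_cpp(index$ptr, base_to_code(base))
  bi_interval(iv[["k"]], iv[["l"]], iv[["s"]])
}

base_to_code <- function(base) {
  b <- match(toupper(base), BASES) - 1L
  if (is.na(b)) stop("base must be one of A, C, G, T", call. = FALSE)
  b
}

#' BWT-extend: grow a pattern by one base
#'
#' Computes the suffix-array interval of `bP` (backward) or `Pb` (forward)
#' from the interval of `P`. Forward extension is realised as backward
#' extension of the reverse-complement companion interval with the
#' complemented base, followed by swapping the interval roles. Extending a
#' size-0 interval yields a size-0 interval.
#'
#' @param index An `fmd_index`.
#' @param interval A `bi_interval` (or numeric `c(k, l, s)`).
#' @param base One of "A", "C", "G", "T".
#' @param direction `"forward"` (append) or `"backward"` (prepend).
#' @return The extended `bi_interval`.
#' @export
bwt_extend <- function(index, interval, base,
                       direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  iv <- fmd_extend_cpp(index$ptr, as.numeric(interval), base_to_code(base),
                       direction == "forward")
  bi_interval(iv[["k"]], iv[["l"]], iv[["s"]])
}

#' Interval of an arbitrary pattern, by chained extension
#'
#' Convenience wrapper applying [bwt_extend()] base by base.
#'
#' @inheritParams bwt_extend
#' @param pattern A string over ACGT.
#' @return A `bi_interval`.
#' @export
pattern_interval <- function(index, pattern,
                             direction = c("backward", "forward")) {
  direction <- match.arg(direction)
  bases <- strsplit(toupper(pattern), "")[[1]]
  if (length(bases) == 0) return(empty_interval(index))
  if (direction == "backward") bases <- rev(bases)
  iv <- base_interval(index, if (direction == "backward") bases[1] else bases[1])
  for (b in bases[-1]) iv <- bwt_extend(index, iv, b, direction)
  iv
}

#' Suffix-array lookup (SAL)
#'
#' Resolves suffix-array ranks to text positions by LF-stepping from the
#' nearest sampled rank.
#'
#' @param index An `fmd_index`.
#' @param ranks Numeric vector of ranks (0-based).
#' @return Numeric vector of text positions (0-based, over the doubled
#'   text; see [map_occurrences()] to convert to reference coordinates).
#' @export
sal <- function(index, ranks) {
  fmd_sal_cpp(index$ptr, as.numeric(ranks))
}

#' Map text occurrences to forward-strand reference coordinates
#'
#' Positions falling in the reverse-complement half of the indexed text are
#' mapped to the leftmost forward-strand coordinate of the occurrence, with
#' the strand reported as `"-"`.
#'
#' @param index An `fmd_index`.
#' @param tpos Text positions (e.g. from [sal()]).
#' @param len Match lengths (recycled).
#' @return A data frame with columns `pos` (0-based reference coordinate)
#'   and `strand` (`"+"`/`"-"`).
#' @export
map_occurrences <- function(index, tpos, len) {
  len <- rep_len(as.numeric(len), length(tpos))
  m <- fmd_map_cpp(index$ptr, as.numeric(tpos), len)
  data.frame(pos = m$pos, strand = ifelse(m$rev, "-", "+"),
             stringsAsFactors = FALSE)
}

#' Occurrences of a pattern on both strands
#'
#' Finds all occurrence positions of `pattern` (and, on the minus strand,
#' of its reverse complement) by chained BWT-extend followed by one SAL per
#' rank of the resulting interval.
#'
#' @inheritParams pattern_interval
#' @return A data frame with columns `pos` and `strand`, sorted.
#' @export
find_occurrences <- function(index, pattern) {
  iv <- pattern_interval(index, pattern)
  if (iv[["s"]] == 0) {
    return(data.frame(pos = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  ranks <- iv[["k"]] + seq_len(iv[["s"]]) - 1
  occ <- map_occurrences(index, sal(index, ranks), nchar(pattern))
  occ[order(occ$pos, occ$strand), , drop = FALSE]
}

#' Save / load an FMD index
#'
#' The index (BWT, sampled suffix array, segment table, reference sequence)
#' is written as a versioned payload. Loading validates the payload and
#' fails on corrupted files rather than returning wrong answers.
#'
#' @param index An `fmd_index`.
#' @param path File path.
#' @return `fmd_save` returns `path` invisibly; `fmd_load` returns the
#'   restored `fmd_index`.
#' @export
fmd_save <- function(index, path) {
  dump <- fmd_dump_cpp(index$ptr)
  payload <- list(magic = "smemcache_fmd", version = 1L, dump = dump,
                  records = index$records, seq = index$seq,
                  sa_sample_interval = index$sa_sample_interval)
  payload$checksum <- index_checksum(payload)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname fmd_save
#' @export
fmd_load <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read index file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(payload) || !identical(payload$magic, "smemcache_fmd")) {
    stop("'", path, "' is not an smemcache index file", call. = FALSE)
  }
  if (!identical(payload$version, 1L)) {
    stop("unsupported index file version", call. = FALSE)
  }
  check <- payload$checksum
  payload$checksum <- NULL
  if (!identical(check, index_checksum(payload))) {
    stop("index file '", path, "' is corrupted (checksum mismatch)",
         call. = FALSE)
  }
  ptr <- fmd_restore_cpp(payload$dump)
  structure(
    list(ptr = ptr, records = payload$records, seq = payload$seq,
         sa_sample_interval = payload$sa_sample_interval),
    class = "fmd_index")
}

index_checksum <- function(payload) {
  d <- payload$dump
  sum(as.numeric(d$bwt)) + sum(d$samp_rank) + sum(d$samp_pos) +
    d$n * 7 + d$half + nchar(payload$seq)
}

#' Reverse complement of a DNA string
#' @param x Character vector over ACGTN.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
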