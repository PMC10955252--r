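# Brute-force oracles, independent of the package's FM-index path.
# Occurrence counts come from naive scans (Biostrings::countPattern) over
# the reference and its reverse complement.

oracle_genome <- function(genome) {
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(genome)))
  n <- nchar(genome)
  list(fwd = Biostrings::DNAString(genome),
       rev = Biostrings::DNAString(rc),
       sfx = c(substring(genome, 1:n, n), substring(rc, 1:n, n)))
}

# naive occurrence count over both strands: how many suffixes of the
# genome or its reverse complement start with the pattern
oracle_count <- function(og, pattern) {
  sum(startsWith(og$sfx, pattern))
}

# Longest end e(i) >= i for each start i such that count(read[i..e)) >= t;
# e(i) is non-decreasing in i, so extensions are amortised O(len) scans.
# Returns 0-based half-open ends; NA where even the single base is dead.
oracle_match_ends <- function(og, read, t = 1) {
  L <- nchar(read)
  ends <- rep(NA_integer_, L)
  e <- 0
  for (i in seq_len(L)) {          # i is 1-based start
    if (e < i) e <- i - 1
    if (e == i - 1) {
      if (oracle_count(og, substring(read, i, i)) < t) next
      e <- i
    }
    while (e < L && oracle_count(og, substring(read, i, e + 1)) >= t) {
      e <- e + 1
    }
    ends[i] <- e
  }
  ends
}

# All maximal exact matches of the read with occurrence count >= t,
# optionally restricted to those covering a pivot (0-based).
# A match (i, e(i)) is maximal iff i is the smallest start achieving e(i).
oracle_maximal_matches <- function(og, read, t = 1, pivot = NULL) {
  ends <- oracle_match_ends(og, read, t)
  out <- data.frame(qbeg = integer(0), qend = integer(0), s = numeric(0))
  for (i in seq_along(ends)) {
    if (is.na(ends[i])) next
    if (i > 1 && !is.na(ends[i - 1]) && ends[i - 1] == ends[i]) next
    qbeg <- i - 1               # to 0-based
    qend <- ends[i]
    if (!is.null(pivot) && !(qbeg <= pivot && pivot < qend)) next
    out <- rbind(out, data.frame(
      qbeg = qbeg, qend = qend,
      s = oracle_count(og, substring(read, i, qend))))
  }
  out
}

# Full SMEM collection oracle: whole-read maximal matches at min_intv,
# plus re-seeding at the middle base of every long SMEM with the count
# raised past the triggering SMEM's, deduplicated, length-filtered.
oracle_collect <- function(og, read, min_seed_len = 19, reseed_r = 1.5,
                           min_intv = 1) {
  first <- oracle_maximal_matches(og, read, t = min_intv)
  first <- first[first$qend - first$qbeg >= min_seed_len, , drop = FALSE]
  extra <- data.frame(qbeg = integer(0), qend = integer(0), s = numeric(0))
  for (j in seq_len(nrow(first))) {
    m <- first[j, ]
    if (m$qend - m$qbeg >= min_seed_len * reseed_r) {
      mid <- floor((m$qbeg + m$qend) / 2)
      rs <- oracle_maximal_matches(og, read, t = m$s + 1, pivot = mid)
      rs <- rs[rs$qend - rs$qbeg >= min_seed_len, , drop = FALSE]
      extra <- rbind(extra, rs)
    }
  }
  all <- rbind(first, extra)
  all <- all[!duplicated(all[, c("qbeg", "qend")]), , drop = FALSE]
  all[order(all$qbeg, all$qend), , drop = FALSE]
}

# --- small fixture builders ------------------------------------------------

random_genome <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# reads drawn from the genome, optionally mutated / reverse-complemented
draw_reads <- function(genome, n, len, error_rate = 0, rc_frac = 0,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(genome)
  pos <- sample.int(L - len + 1, n, replace = TRUE)
  reads <- substring(genome, pos, pos + len - 1)
  if (error_rate > 0) {
    for (i in seq_len(n)) {
      hit <- which(runif(len) < error_rate)
      for (h in hit) {
        old <- substring(reads[i], h, h)
        substring(reads[i], h, h) <-
          sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
    }
  }
  if (rc_frac > 0) {
    flip <- runif(n) < rc_frac
    reads[flip] <- smemcache::revcomp(reads[flip])
  }
  reads
}

# reconstruct the documented index text layout (forward half F = segment
# + separator, then the reverse complement of F with separators mirrored,
# then the sentinel) with digit symbols whose ASCII order matches the
# index's symbol order, and sort suffixes naively
naive_text_sa <- function(g) {
  code <- chartr("ACGT", "2345", g)
  rcode <- chartr("ACGT", "2345", smemcache::revcomp(g))
  text <- paste0(code, "1", "1", rcode, "0")
  n <- nchar(text)
  order(substring(text, 1:n, n)) - 1  # 0-based suffix start positions
}

smem_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(paste(df$qbeg, df$qend, df$s, sep = ":"))
}
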