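# Independent oracles used to anchor the implementation.
# These deliberately share no code with the package internals.

# Exhaustive ungapped best-hit scan: tries every offset of every record on
# both strands, counting mismatches directly, with tie-break
# (mismatches, record order, leftmost, '+' first). O(L * l) per read.
oracle_align <- function(reads, reference, max_mismatches) {
  seqs <- if (inherits(reads, "read_set")) reads$sequences else reads
  refs <- lapply(as.character(reference$sequences),
                 function(s) strsplit(s, NULL)[[1]])
  rc <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, NULL)[[1]]),
                                                 collapse = ""))
  rows <- lapply(seq_along(seqs), function(i) {
    q_fwd <- as.character(seqs[[i]])
    best <- list(mm = max_mismatches + 1L, rec = NA_integer_,
                 pos = NA_integer_, strand = NA_character_)
    for (strand in c("+", "-")) {
      q <- strsplit(if (strand == "+") q_fwd else rc(q_fwd), NULL)[[1]]
      l <- length(q)
      for (r in seq_along(refs)) {
        rv <- refs[[r]]
        L <- length(rv)
        if (l > L) next
        n_off <- L - l + 1L
        mism <- integer(n_off)
        for (j in seq_len(l)) {
          mism <- mism + (rv[j:(n_off + j - 1L)] != q[j])
        }
        for (off in seq_len(n_off)) {
          mm <- mism[off]
          if (mm > max_mismatches) next
          better <- mm < best$mm ||
            (mm == best$mm && (r < best$rec ||
              (r == best$rec && (off - 1L < best$pos ||
                (off - 1L == best$pos && strand == "+" &&
                   best$strand == "-")))))
          if (better) {
            best <- list(mm = mm, rec = r, pos = off - 1L, strand = strand)
          }
        }
      }
    }
    mapped <- !is.na(best$rec)
    data.frame(
      read_id = names(seqs)[i], mapped = mapped,
      record_id = if (mapped) reference$records$record_id[best$rec]
                  else NA_character_,
      start = if (mapped) best$pos else NA_integer_,
      strand = if (mapped) best$strand else NA_character_,
      mismatches = if (mapped) best$mm else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Exhaustive enumeration of the two-read no-overlap probability: counts
# ordered start pairs (a, b) with |a - b| >= l over all s^2 pairs.
oracle_no_overlap_n2 <- function(l, L) {
  s <- L - l + 1
  a <- rep(seq_len(s), each = s)
  b <- rep(seq_len(s), times = s)
  mean(abs(a - b) >= l)
}

# Monte-Carlo estimate of the n-read no-overlap probability with its
# standard error.
oracle_no_overlap_mc <- function(n, l, L, trials = 1e5) {
  s <- L - l + 1
  hits <- vapply(seq_len(trials), function(i) {
    starts <- sort.int(sample.int(s, n, replace = TRUE))
    all(diff(starts) >= l)
  }, TRUE)
  p <- mean(hits)
  list(p = p, se = sqrt(p * (1 - p) / trials))
}

# Random mutated copy of a genome substring: returns sequence with exactly
# n_mut distinct substituted positions.
mutate_substring <- function(genome_chars, start0, len, n_mut) {
  q <- genome_chars[(start0 + 1):(start0 + len)]
  if (n_mut > 0) {
    at <- sample.int(len, n_mut)
    q[at] <- vapply(q[at], function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                      b), 1), "")
  }
  paste(q, collapse = "")
}
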