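# Shared fixture builders (all fixtures are generated in code).

# A small hand-specified catalog: two species, one with two chromosomes.
tiny_catalog <- function() {
  seqs <- Biostrings::DNAStringSet(c(
    chrA1 = "ACGTACGTACGTACGTACGTGGGTTTAAACCCGGGTTTAAACCC",
    chrA2 = "TTTTGGGGCCCCAAAATTTTGGGGCCCCAAAATTTTGGGG",
    chrB1 = "GATCGATCGATCGATCGATCAAATTTCCCGGGAAATTTCCCGGG"
  ))
  reference_catalog(seqs, data.frame(
    record_id = c("chrA1", "chrA2", "chrB1"),
    organism_name = c("Examplea prima X1", "Examplea prima X1",
                      "Examplea secunda Y9"),
    stringsAsFactors = FALSE
  ))
}

# Random catalog for aligner property tests.
random_catalog <- function(n_rec = 2, len = 3000, seed = 1) {
  set.seed(seed)
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(n_rec), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, ""))
  names(seqs) <- sprintf("rec%02d", seq_len(n_rec))
  reference_catalog(seqs, data.frame(
    record_id = names(seqs),
    organism_name = sprintf("Testus species%02d st%02d", seq_len(n_rec),
                            seq_len(n_rec)),
    stringsAsFactors = FALSE
  ))
}

# Minimal alignment_frame builder for attribution tests.
aln_frame <- function(read_id, record_id, start = 0L, strand = "+",
                      mismatches = 0L) {
  n <- length(read_id)
  mapped <- !is.na(record_id)
  start <- rep_len(as.integer(start), n)
  strand <- rep_len(strand, n)
  mismatches <- rep_len(as.integer(mismatches), n)
  start[!mapped] <- NA_integer_
  strand[!mapped] <- NA_character_
  mismatches[!mapped] <- NA_integer_
  out <- data.frame(
    read_id = read_id, mapped = mapped,
    record_id = record_id,
    start = start, strand = strand, mismatches = mismatches,
    is_primary = rep_len(TRUE, n), stringsAsFactors = FALSE
  )
  class(out) <- c("alignment_frame", "data.frame")
  out
}
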