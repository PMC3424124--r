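#' Generate random genomes for a synthetic mock community
#'
#' Draws independent uniform-base genomes, one species per genome. Random
#' sequences of this length are effectively orthogonal: a 50 bp read from
#' one genome essentially never aligns to another within a small mismatch
#' budget, so the generator yields a community where species attribution
#' has a known, clean truth.
#'
#' @param n_species number of genomes.
#' @param genome_length genome length in bp (single value or vector).
#' @param seed integer seed (mandatory; the generator is deterministic).
#' @param species_names optional species names; default "Species sim<i>".
#' @return a \code{reference_catalog} with one record per species.
#' @export
simulate_genomes <- function(n_species, genome_length = 1e6, seed,
                             species_names = NULL) {
  stopifnot(n_species >= 1, all(genome_length >= 1))
  if (missing(seed)) stop("seed is mandatory")
  lens <- rep_len(as.integer(genome_length), n_species)
  if (is.null(species_names)) {
    species_names <- sprintf("Genus%02d species%02d", seq_len(n_species),
                             seq_len(n_species))
  }
  set.seed(seed)
  seqs <- Biostrings::DNAStringSet(vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, ""))
  ids <- sprintf("chr_sim%02d", seq_len(n_species))
  names(seqs) <- ids
  reference_catalog(seqs, data.frame(
    record_id = ids,
    organism_name = paste(species_names, "simstrain"),
    stringsAsFactors = FALSE
  ))
}

#' A set of reads with optional truth labels
#'
#' @param sequences named [Biostrings::DNAStringSet] (names = read ids).
#' @param truth optional data.frame with columns \code{read_id,
#'   species_key, record_id, start, strand} (0-based starts).
#' @return object of class \code{read_set}.
#' @export
read_set <- function(sequences, truth = NULL) {
  stopifnot(methods::is(sequences, "DNAStringSet"))
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("reads must be uniquely named")
  }
  if (!is.null(truth)) {
    stopifnot(all(c("read_id", "species_key", "record_id",
                    "start", "strand") %in% names(truth)))
    truth <- truth[match(names(sequences), truth$read_id), , drop = FALSE]
    if (anyNA(truth$read_id)) stop("truth table does not cover all reads")
  }
  structure(list(sequences = sequences, truth = truth), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads%s\n", length(x$sequences),
              if (is.null(x$truth)) "" else " (with truth labels)"))
  invisible(x)
}

#' @export
length.read_set <- function(x) length(x$sequences)

#' Simulate a mock-community read set with substitution errors
#'
#' Draws reads from the catalog genomes according to a community design
#' (per-record or per-species read counts). Start positions are uniform
#' over the valid starts of each source record, strands are uniform, and
#' each base is independently substituted to a uniformly chosen different
#' base with probability \code{sub_rate}. Truth labels are embedded in the
#' read id (\code{<record_id>|<start>|<strand>|<serial>}) and returned as a
#' truth table, so downstream SAM files retain the ground truth.
#'
#' A design row naming a species key is expanded to that species' records;
#' when a species has several records the count is split proportionally to
#' record length (largest remainders), mimicking uniform sampling from the
#' whole genome.
#'
#' @param catalog a \code{reference_catalog} of source genomes.
#' @param design data.frame with columns \code{id} (record_id or
#'   species_key) and \code{read_count}.
#' @param read_length read length in bp.
#' @param sub_rate per-base substitution probability in [0, 1).
#' @param seed integer seed (mandatory).
#' @return a \code{read_set} with truth labels.
#' @export
simulate_reads <- function(catalog, design, read_length = 50,
                           sub_rate = 0.01, seed) {
  stopifnot(inherits(catalog, "reference_catalog"),
            all(c("id", "read_count") %in% names(design)),
            read_length >= 1, sub_rate >= 0, sub_rate < 1)
  if (missing(seed)) stop("seed is mandatory")
  rec <- catalog$records
  # expand species-level design rows to records
  rows <- list()
  for (i in seq_len(nrow(design))) {
    id <- design$id[i]
    n <- as.integer(design$read_count[i])
    stopifnot(n >= 0)
    if (id %in% rec$record_id) {
      rows[[length(rows) + 1L]] <- data.frame(record_id = id, n = n)
    } else if (id %in% rec$species_key) {
      rids <- rec$record_id[rec$species_key == id]
      lens <- as.numeric(rec$length[match(rids, rec$record_id)])
      frac <- n * lens / sum(lens)
      nn <- floor(frac)
      rem <- n - sum(nn)
      if (rem > 0) {
        top <- order(frac - nn, decreasing = TRUE)[seq_len(rem)]
        nn[top] <- nn[top] + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(record_id = rids, n = nn)
    } else {
      stop("design id absent from catalog: ", id)
    }
  }
  plan <- do.call(rbind, rows)
  plan <- plan[plan$n > 0, , drop = FALSE]
  lens <- rec$length[match(plan$record_id, rec$record_id)]
  if (any(read_length > lens)) {
    stop("read_length exceeds the shortest requested genome")
  }

  set.seed(seed)
  all_seq <- vector("list", nrow(plan))
  all_truth <- vector("list", nrow(plan))
  serial0 <- 0L
  for (i in seq_len(nrow(plan))) {
    rid <- plan$record_id[i]
    n <- plan$n[i]
    L <- lens[i]
    starts <- sample.int(L - read_length + 1L, n, replace = TRUE) - 1L
    strands <- ifelse(stats::runif(n) < 0.5, "+", "-")
    views <- Biostrings::extractAt(
      catalog$sequences[[rid]],
      IRanges::IRanges(start = starts + 1L, width = read_length)
    )
    minus <- strands == "-"
    if (any(minus)) {
      views[minus] <- Biostrings::reverseComplement(views[minus])
    }
    ids <- sprintf("%s|%d|%s|%d", rid, starts, strands,
                   serial0 + seq_len(n))
    serial0 <- serial0 + n
    names(views) <- ids
    all_seq[[i]] <- views
    all_truth[[i]] <- data.frame(
      read_id = ids,
      species_key = rec$species_key[match(rid, rec$record_id)],
      record_id = rid, start = starts, strand = strands,
      stringsAsFactors = FALSE
    )
  }
  seqs <- do.call(c, all_seq)
  truth <- do.call(rbind, all_truth)

  if (sub_rate > 0 && length(seqs) > 0) {
    seqs <- inject_substitutions(seqs, sub_rate)
  }
  read_set(seqs, truth)
}

# Flip each base independently with probability `rate` to a uniformly chosen
# different base. Operates on the concatenation for speed.
inject_substitutions <- function(seqs, rate) {
  widths <- Biostrings::width(seqs)
  big <- Biostrings::DNAString(paste(as.character(seqs), collapse = ""))
  total <- length(big)
  hit <- which(stats::runif(total) < rate)
  if (length(hit)) {
    old <- strsplit(as.character(Biostrings::extractAt(
      big, IRanges::IRanges(hit, width = 1L)
    )), NULL)
    old <- vapply(old, `[[`, "", 1L)
    bases <- c("A", "C", "G", "T")
    pick <- vapply(old, function(b) {
      alt <- setdiff(bases, b)
      if (length(alt) == 0L) b else sample(alt, 1L)
    }, "", USE.NAMES = FALSE)
    big <- Biostrings::replaceLetterAt(big, hit, paste(pick, collapse = ""))
  }
  ends <- cumsum(widths)
  out <- Biostrings::DNAStringSet(big, start = ends - widths + 1L,
                                  end = ends)
  names(out) <- names(seqs)
  out
}

#' Trim reads to a fixed short-read window
#'
#' Extracts bases \code{[offset, offset + target_length)} (0-based) from
#' each read; reads too short for the window are dropped and counted.
#' Typical uses: take the first 50 bp of longer reads (\code{offset = 0}),
#' or cut 50-mers out of Sanger reads at position 100 to avoid ambiguous
#' bases near read starts.
#'
#' @param reads a \code{read_set} or \code{DNAStringSet}.
#' @param target_length window length (>= 1).
#' @param offset 0-based window start (>= 0).
#' @return a \code{read_set}; attribute \code{dropped} counts reads shorter
#'   than \code{offset + target_length}.
#' @export
trim_reads <- function(reads, target_length, offset = 0L) {
  stopifnot(target_length >= 1, offset >= 0)
  seqs <- if (inherits(reads, "read_set")) reads$sequences else reads
  truth <- if (inherits(reads, "read_set")) reads$truth else NULL
  need <- offset + target_length
  keep <- Biostrings::width(seqs) >= need
  n_drop <- sum(!keep)
  if (n_drop) {
    message(n_drop, " read(s) shorter than ", need, " bp dropped")
  }
  seqs <- seqs[keep]
  out <- Biostrings::subseq(seqs, start = offset + 1L,
                            width = target_length)
  if (!is.null(truth)) truth <- truth[keep, , drop = FALSE]
  res <- read_set(out, truth)
  attr(res, "dropped") <- n_drop
  res
}

#' Write a read set to FASTA or FASTQ
#'
#' FASTQ output carries a constant quality of 'I' (Phred 40); the simulator
#' does not model qualities.
#'
#' @param reads a \code{read_set}.
#' @param path output path; format chosen by extension (.fq/.fastq = FASTQ).
#' @param truth_path optional path for the sidecar truth TSV.
#' @return invisibly, \code{path}.
#' @export
write_reads <- function(reads, path, truth_path = NULL) {
  stopifnot(inherits(reads, "read_set"))
  fastq <- grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)
  if (fastq) {
    quals <- Biostrings::BStringSet(vapply(
      Biostrings::width(reads$sequences),
      function(w) strrep("I", w), ""
    ))
    Biostrings::writeXStringSet(reads$sequences, path, format = "fastq",
                                qualities = quals)
  } else {
    Biostrings::writeXStringSet(reads$sequences, path)
  }
  if (!is.null(truth_path)) {
    if (is.null(reads$truth)) stop("read set has no truth labels")
    utils::write.table(reads$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a FASTA/FASTQ read file (optionally with its truth table)
#'
#' @param path reads file; format chosen by extension.
#' @param truth_path optional truth TSV from [write_reads()].
#' @return a \code{read_set}.
#' @export
read_reads <- function(path, truth_path = NULL) {
  fastq <- grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)
  seqs <- if (fastq) {
    Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    Biostrings::readDNAStringSet(path)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  truth <- NULL
  if (!is.null(truth_path)) {
    truth <- utils::read.delim(truth_path, stringsAsFactors = FALSE)
  }
  read_set(seqs, truth)
}

#' The ten-strain ocean mock-community design
#'
#' The published per-strain read counts of the simulated ocean metagenome
#' (100,000 reads total across ten marine strains), used as the default
#' benchmark community design.
#'
#' @return data.frame with columns \code{id} (species key) and
#'   \code{read_count}; counts sum to 100,000.
#' @export
ocean_design <- function() {
  data.frame(
    id = c("Marinomonas sp. MWYL1", "Shewanella loihica",
           "Oceanobacillus iheyensis", "Nitrosococcus oceani",
           "Alcanivorax borkumensis", "Synechococcus elongatus",
           "Halobacterium salinarum", "Prochlorococcus marinus",
           "Nitrosopumilus maritimus", "Candidatus Pelagibacter ubique"),
    read_count = c(17391L, 15665L, 12473L, 11890L, 10509L,
                   9252L, 6911L, 5946L, 5619L, 4344L),
    stringsAsFactors = FALSE
  )
}
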