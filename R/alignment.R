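#' Align reads with the built-in ungapped k-mismatch aligner
#'
#' A self-contained stand-in for an external short-read aligner: for each
#' read it reports the single best ungapped placement (fewest mismatches
#' over both strands) with at most \code{max_mismatches} mismatches, or
#' marks the read unmapped. Ties are broken deterministically by record
#' order, then leftmost position, then forward strand. Candidate placements
#' are found by the pigeonhole principle (k+1 non-overlapping exact seeds),
#' so results agree exactly with an exhaustive scan.
#'
#' Minus-strand placements report the 0-based leftmost reference position
#' of the reverse-complemented read, as in SAM.
#'
#' @param reads a \code{read_set} or named \code{DNAStringSet}.
#' @param reference a \code{reference_catalog}.
#' @param max_mismatches maximum mismatches k (small, typically 0-3).
#' @return data.frame of class \code{alignment_frame} with columns
#'   \code{read_id, mapped, record_id, start, strand, mismatches,
#'   is_primary} (one row per read; unmapped rows carry NA placement).
#' @export
builtin_align <- function(reads, reference, max_mismatches = 3L) {
  seqs <- if (inherits(reads, "read_set")) reads$sequences else reads
  stopifnot(inherits(reference, "reference_catalog"),
            max_mismatches >= 0)
  res <- cpp_builtin_align(as.character(reference$sequences),
                           as.character(seqs),
                           as.integer(max_mismatches))
  out <- data.frame(
    read_id = names(seqs),
    mapped = res$mapped,
    record_id = ifelse(res$mapped,
                       reference$records$record_id[res$ref_index],
                       NA_character_),
    start = res$start,
    strand = res$strand,
    mismatches = res$mismatches,
    is_primary = TRUE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("alignment_frame", "data.frame")
  out
}

#' Write alignments as a minimal SAM file
#'
#' Emits mandatory fields plus the NM tag; minus-strand records carry the
#' reverse-complemented (forward-strand) sequence as the SAM standard
#' requires.
#'
#' @param alignments an \code{alignment_frame} (from [builtin_align()]).
#' @param reads the \code{read_set}/\code{DNAStringSet} that was aligned.
#' @param reference the \code{reference_catalog} aligned against.
#' @param path output SAM path.
#' @return invisibly, \code{path}.
#' @export
write_sam <- function(alignments, reads, reference, path) {
  seqs <- if (inherits(reads, "read_set")) reads$sequences else reads
  stopifnot(all(alignments$read_id %in% names(seqs)))
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", reference$records$record_id,
            reference$records$length),
    "@PG\tID:metashot\tPN:metashot"
  )
  seqc <- as.character(seqs[alignments$read_id])
  minus <- alignments$mapped & alignments$strand == "-"
  if (any(minus)) {
    seqc[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqc[minus])
    ))
  }
  flag <- ifelse(!alignments$mapped, 4L, ifelse(minus, 16L, 0L))
  lines <- ifelse(
    alignments$mapped,
    sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
            alignments$read_id, flag, alignments$record_id,
            alignments$start + 1L, nchar(seqc), seqc,
            alignments$mismatches),
    sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*",
            alignments$read_id, seqc)
  )
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read primary alignments from a SAM or BAM file
#'
#' Normalises alignments to the internal 0-based representation: SAM's
#' 1-based POS becomes a 0-based start, records with the unmapped flag
#' yield \code{mapped = FALSE}, and secondary (0x100) and supplementary
#' (0x800) records are excluded so at most one record per read remains.
#' Mismatch counts come from the NM tag when present (NA otherwise).
#'
#' @param path a .sam (text) or .bam file. BAM requires the Rsamtools
#'   package.
#' @return an \code{alignment_frame}.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    return(read_alignments_bam(path))
  }
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  body_idx <- which(!is_header & nzchar(lines))
  recs <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(recs)
  if (any(nf < 11L)) {
    bad <- body_idx[which(nf < 11L)[1L]]
    stop("malformed SAM record (fewer than 11 fields) at line ", bad)
  }
  flag <- suppressWarnings(as.integer(vapply(recs, `[[`, "", 2L)))
  pos <- suppressWarnings(as.integer(vapply(recs, `[[`, "", 4L)))
  if (anyNA(flag) || anyNA(pos)) {
    bad <- body_idx[which(is.na(flag) | is.na(pos))[1L]]
    stop("malformed SAM record (non-numeric FLAG or POS) at line ", bad)
  }
  keep <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L
  recs <- recs[keep]; flag <- flag[keep]; pos <- pos[keep]
  mapped <- bitwAnd(flag, 0x4L) == 0L
  nm <- vapply(recs, function(f) {
    if (length(f) > 11L) {
      hit <- grep("^NM:i:", f[12:length(f)], value = TRUE)
      if (length(hit)) return(as.integer(sub("^NM:i:", "", hit[1L])))
    }
    NA_integer_
  }, 1L)
  out <- data.frame(
    read_id = vapply(recs, `[[`, "", 1L),
    mapped = mapped,
    record_id = ifelse(mapped, vapply(recs, `[[`, "", 3L), NA_character_),
    start = ifelse(mapped, pos - 1L, NA_integer_),
    strand = ifelse(mapped,
                    ifelse(bitwAnd(flag, 0x10L) != 0L, "-", "+"),
                    NA_character_),
    mismatches = ifelse(mapped, nm, NA_integer_),
    is_primary = TRUE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("alignment_frame", "data.frame")
  out
}

read_alignments_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading BAM requires the Rsamtools package; ",
         "convert to SAM (samtools view -h) or install Rsamtools")
  }
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand"),
    tag = "NM", flag = flags
  )
  b <- Rsamtools::scanBam(path, param = param)[[1L]]
  mapped <- bitwAnd(b$flag, 0x4L) == 0L
  nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(b$qname))
  out <- data.frame(
    read_id = b$qname,
    mapped = mapped,
    record_id = ifelse(mapped, as.character(b$rname), NA_character_),
    start = ifelse(mapped, b$pos - 1L, NA_integer_),
    strand = ifelse(mapped, as.character(b$strand), NA_character_),
    mismatches = ifelse(mapped, nm, NA_integer_),
    is_primary = TRUE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("alignment_frame", "data.frame")
  out
}

#' Run an external SAM-emitting aligner
#'
#' Thin adapter around a command template. The template receives the reads
#' path, the index/reference prefix and the output path via the
#' placeholders \code{{reads}}, \code{{index}} and \code{{out}}; any extra
#' parameter string is substituted for \code{{extra}} verbatim, giving
#' complete pass-through access to the aligner's own options. The executed
#' command line is logged via \code{message()}.
#'
#' There is no automatic fallback to the built-in aligner: a missing
#' executable is an error naming the tool.
#'
#' @param reads_path path to the reads file.
#' @param index_prefix aligner index or reference prefix.
#' @param out_sam output SAM path.
#' @param template command template, e.g.
#'   \code{"bowtie -S {extra} {index} {reads} {out}"}.
#' @param extra extra parameter string passed through verbatim.
#' @return \code{out_sam} (invisibly) on success.
#' @export
invoke_external_aligner <- function(reads_path, index_prefix, out_sam,
                                    template, extra = "") {
  cmd <- template
  for (sub in list(c("{reads}", reads_path), c("{index}", index_prefix),
                   c("{out}", out_sam), c("{extra}", extra))) {
    cmd <- gsub(sub[1L], sub[2L], cmd, fixed = TRUE)
  }
  exe <- strsplit(trimws(cmd), "\\s+")[[1L]][1L]
  if (Sys.which(exe) == "" && !file.exists(exe)) {
    stop("external aligner executable not found: '", exe,
         "'. Install it, fix the command template, or use builtin_align().")
  }
  message("[metashot] running: ", cmd)
  status <- system(paste(cmd, "2> /tmp/metashot_aligner.stderr"))
  if (status != 0L) {
    err <- tryCatch(readLines("/tmp/metashot_aligner.stderr"),
                    error = function(e) character(0))
    stop("external aligner exited with status ", status, ":\n",
         paste(err, collapse = "\n"))
  }
  if (!file.exists(out_sam)) {
    stop("external aligner did not produce the expected SAM: ", out_sam)
  }
  invisible(out_sam)
}
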