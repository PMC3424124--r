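#' Roll primary alignments up to per-species read counts
#'
#' The core of the method: every mapped primary alignment increments the
#' count of the species its reference record belongs to, so counts over
#' multiple chromosomes — or multiple strains sharing one species key — are
#' summed in a single species row. Unmapped reads enter the totals only.
#'
#' @param alignments an \code{alignment_frame} (one primary record per
#'   read).
#' @param metadata data.frame mapping \code{record_id} to
#'   \code{species_key} (e.g. from [read_reference_meta()] or a catalog's
#'   \code{records}).
#' @return object of class \code{species_count_table}: a data.frame with
#'   columns \code{species_key, read_count, fraction_of_total}, sorted by
#'   count descending (ties by species key), with attributes
#'   \code{total_reads}, \code{mapped_reads}, \code{unmapped_reads} and a
#'   per-record sub-table \code{record_counts}.
#' @export
count_by_species <- function(alignments, metadata) {
  stopifnot(all(c("record_id", "species_key") %in% names(metadata)))
  mapped <- alignments[alignments$mapped, , drop = FALSE]
  unknown <- setdiff(mapped$record_id, metadata$record_id)
  if (length(unknown)) {
    stop("alignment record_id(s) missing from metadata: ",
         paste(unknown, collapse = ", "))
  }
  sp <- metadata$species_key[match(mapped$record_id, metadata$record_id)]
  total <- nrow(alignments)
  n_mapped <- nrow(mapped)
  if (n_mapped) {
    counts <- as.data.frame(table(species_key = sp),
                            stringsAsFactors = FALSE)
    names(counts)[2L] <- "read_count"
    rec_counts <- as.data.frame(table(record_id = mapped$record_id),
                                stringsAsFactors = FALSE)
    names(rec_counts)[2L] <- "read_count"
    rec_counts$species_key <- metadata$species_key[
      match(rec_counts$record_id, metadata$record_id)
    ]
  } else {
    counts <- data.frame(species_key = character(0),
                         read_count = integer(0))
    rec_counts <- data.frame(record_id = character(0),
                             read_count = integer(0),
                             species_key = character(0))
  }
  counts <- counts[order(-counts$read_count, counts$species_key), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  counts$fraction_of_total <- if (total > 0) {
    counts$read_count / total
  } else {
    numeric(0)
  }
  structure(counts,
            total_reads = total,
            mapped_reads = n_mapped,
            unmapped_reads = total - n_mapped,
            record_counts = rec_counts,
            class = c("species_count_table", "data.frame"))
}

#' @export
print.species_count_table <- function(x, ...) {
  cat(sprintf(
    "species_count_table: %d species; %d/%d reads mapped (%.1f%%)\n",
    nrow(x), attr(x, "mapped_reads"), attr(x, "total_reads"),
    if (attr(x, "total_reads") > 0) {
      100 * attr(x, "mapped_reads") / attr(x, "total_reads")
    } else 0
  ))
  print.data.frame(utils::head(as.data.frame(x), 20L))
  if (nrow(x) > 20L) cat("... (", nrow(x) - 20L, " more rows)\n", sep = "")
  invisible(x)
}

#' Apply the read-count detection threshold
#'
#' A species is reported present when its mapped-read count reaches the
#' threshold (inclusive: a count of exactly \code{min_reads} is detected).
#' The default of 100 reads reflects that roughly 100 aligned short reads
#' suffice to estimate the length and abundance of the underlying taxon.
#'
#' @param table a \code{species_count_table}.
#' @param min_reads detection threshold (>= 0), default 100.
#' @return character vector of detected species keys, ordered by count
#'   descending (ties by species key).
#' @export
detect_species <- function(table, min_reads = 100L) {
  stopifnot(min_reads >= 0)
  hit <- table[table$read_count >= min_reads, , drop = FALSE]
  hit <- hit[order(-hit$read_count, hit$species_key), , drop = FALSE]
  hit$species_key
}

#' Remove reads that align to a decoy (contaminant) reference
#'
#' Screens a read set against alignments computed on a decoy reference
#' (for example the human genome, or cloning vectors): any read with a
#' mapped primary decoy alignment is removed. The partition is exact —
#' retained and removed reads are disjoint and jointly cover the input.
#'
#' @param reads a \code{read_set}.
#' @param decoy_alignments an \code{alignment_frame} computed against the
#'   decoy reference. Read ids absent from the read set are ignored with a
#'   warning.
#' @return list with \code{retained} and \code{removed} (both
#'   \code{read_set}s).
#' @export
filter_reads_by_reference <- function(reads, decoy_alignments) {
  stopifnot(inherits(reads, "read_set"))
  ids <- names(reads$sequences)
  stray <- setdiff(decoy_alignments$read_id, ids)
  if (length(stray)) {
    warning(length(stray),
            " decoy alignment read id(s) absent from the read set; ignored",
            call. = FALSE)
  }
  hit <- decoy_alignments$read_id[decoy_alignments$mapped &
                                    decoy_alignments$read_id %in% ids]
  removed <- ids %in% hit
  subset_rs <- function(sel) {
    read_set(reads$sequences[sel],
             if (is.null(reads$truth)) NULL else
               reads$truth[sel, , drop = FALSE])
  }
  list(retained = subset_rs(!removed), removed = subset_rs(removed))
}

#' Per-read species assignment
#'
#' Maps each read to the species of its primary alignment; unmapped reads
#' get NA. This is the per-read view behind [count_by_species()], used for
#' read-level accuracy scoring.
#'
#' @param alignments an \code{alignment_frame}.
#' @param metadata record_id to species_key table.
#' @return data.frame with columns \code{read_id, species_key}.
#' @export
assign_reads <- function(alignments, metadata) {
  sp <- rep(NA_character_, nrow(alignments))
  m <- alignments$mapped
  sp[m] <- metadata$species_key[match(alignments$record_id[m],
                                      metadata$record_id)]
  data.frame(read_id = alignments$read_id, species_key = sp,
             stringsAsFactors = FALSE)
}

#' Write a species count table (and its per-record sub-table) to TSV
#'
#' @param table a \code{species_count_table}.
#' @param out_prefix writes \code{<prefix>.species.tsv} and
#'   \code{<prefix>.records.tsv}.
#' @param manifest optional manifest filename recorded in a header comment.
#' @return invisibly, the two paths.
#' @export
write_species_table <- function(table, out_prefix, manifest = NULL) {
  sp_path <- paste0(out_prefix, ".species.tsv")
  rec_path <- paste0(out_prefix, ".records.tsv")
  hdr <- c(
    if (!is.null(manifest)) paste0("# manifest: ", manifest),
    sprintf("# total_reads=%d mapped_reads=%d unmapped_reads=%d",
            attr(table, "total_reads"), attr(table, "mapped_reads"),
            attr(table, "unmapped_reads"))
  )
  for (p in list(list(sp_path, as.data.frame(table)),
                 list(rec_path, attr(table, "record_counts")))) {
    con <- file(p[[1L]], "w")
    writeLines(hdr, con)
    utils::write.table(p[[2L]], con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(c(species = sp_path, records = rec_path))
}
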