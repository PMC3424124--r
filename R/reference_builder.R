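#' Parse a free-text organism description into species key and strain label
#'
#' Splits an organism description (typically a FASTA header or a metadata
#' field) into a normalized species-level key and the remaining strain
#' label. The species key is the binomial "Genus species"; when the epithet
#' is the placeholder \code{"sp."} the following token is kept in the key
#' (so \code{"Marinomonas sp. MWYL1"} is a species-level entity of its own),
#' and a leading \code{"Candidatus"} is retained as part of the key. All
#' remaining tokens form the strain label.
#'
#' @param description character vector of organism descriptions.
#' @return a data.frame with columns \code{species_key} and
#'   \code{strain_label}, one row per input.
#' @examples
#' parse_organism_name("Halobacterium salinarum R1")
#' parse_organism_name("Marinomonas sp. MWYL1")
#' @export
parse_organism_name <- function(description) {
  stopifnot(is.character(description), all(nzchar(trimws(description))))
  out <- lapply(description, function(d) {
    toks <- strsplit(trimws(d), "\\s+")[[1]]
    n_key <- 2L
    if (identical(tolower(toks[1]), "candidatus")) n_key <- 3L
    if (length(toks) >= n_key && tolower(toks[n_key]) == "sp.") {
      n_key <- n_key + 1L
    }
    if (length(toks) < n_key) {
      if (length(toks) == 1L) {
        warning("single-token organism description: ", d, call. = FALSE)
      }
      n_key <- length(toks)
    }
    c(
      species_key = paste(toks[seq_len(n_key)], collapse = " "),
      strain_label = paste(toks[-seq_len(n_key)], collapse = " ")
    )
  })
  data.frame(
    species_key = vapply(out, `[[`, "", "species_key"),
    strain_label = vapply(out, `[[`, "", "strain_label"),
    stringsAsFactors = FALSE
  )
}

#' Build a reference catalog from sequences and metadata
#'
#' A reference catalog couples genome sequences (one record per chromosome
#' or replicon) with species-level metadata. It is the classification
#' universe: reads are attributed to the species keys recorded here.
#'
#' @param sequences a named [Biostrings::DNAStringSet]; names are record ids.
#' @param metadata data.frame with columns \code{record_id},
#'   \code{organism_name}, and optionally \code{strain} and \code{date}
#'   (ISO-8601 release date). Species keys and strain labels are derived
#'   from \code{organism_name} via [parse_organism_name()]; an explicit
#'   \code{strain} column overrides the parsed strain label when non-empty.
#' @return an object of class \code{reference_catalog}: a list with
#'   \code{records} (data.frame: record_id, organism_name, species_key,
#'   strain_label, release_date, length) and \code{sequences}.
#' @export
reference_catalog <- function(sequences, metadata) {
  stopifnot(methods::is(sequences, "DNAStringSet"))
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sequences must be uniquely named by record_id")
  }
  stopifnot(all(c("record_id", "organism_name") %in% names(metadata)))
  if (anyDuplicated(metadata$record_id)) {
    stop("duplicate record_id in metadata")
  }
  missing <- setdiff(ids, metadata$record_id)
  if (length(missing)) {
    stop("records missing from metadata: ", paste(missing, collapse = ", "))
  }
  metadata <- metadata[match(ids, metadata$record_id), , drop = FALSE]
  parsed <- parse_organism_name(metadata$organism_name)
  strain <- parsed$strain_label
  if ("strain" %in% names(metadata)) {
    explicit <- !is.na(metadata$strain) & nzchar(metadata$strain)
    strain[explicit] <- metadata$strain[explicit]
  }
  date <- if ("date" %in% names(metadata)) {
    as.Date(as.character(metadata$date))
  } else {
    as.Date(rep(NA_character_, nrow(metadata)))
  }
  records <- data.frame(
    record_id = metadata$record_id,
    organism_name = metadata$organism_name,
    species_key = parsed$species_key,
    strain_label = strain,
    release_date = date,
    length = Biostrings::width(sequences),
    stringsAsFactors = FALSE
  )
  structure(list(records = records, sequences = sequences),
            class = "reference_catalog")
}

#' @export
print.reference_catalog <- function(x, ...) {
  cat(sprintf(
    "reference_catalog: %d records, %d species, %.2f Mb total\n",
    nrow(x$records), length(unique(x$records$species_key)),
    sum(x$records$length) / 1e6
  ))
  invisible(x)
}

#' Species index of a catalog
#'
#' @param catalog a \code{reference_catalog}.
#' @return named list mapping species_key to the record ids carrying it.
#' @export
species_index <- function(catalog) {
  split(catalog$records$record_id, catalog$records$species_key)
}

#' Read a genome collection from FASTA + metadata TSV
#'
#' @param fasta path to a multi-record FASTA file.
#' @param meta path to a tab-separated metadata table with header
#'   \code{record_id, organism_name, strain, date}. FASTA record ids are the
#'   first whitespace-delimited token of each header.
#' @return a \code{reference_catalog}.
#' @export
read_genomes <- function(fasta, meta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  md <- utils::read.delim(meta, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#")
  reference_catalog(seqs, md)
}

#' Select one representative strain per species
#'
#' For every species in the catalog, keeps all records (chromosomes) of
#' exactly one strain: the strain with the earliest release date. Strains
#' with no release date sort last; when no strain of a species has a date,
#' the lexicographically smallest strain label wins (with a warning). Ties
#' on date are broken by strain label, so selection is deterministic.
#'
#' @param catalog a \code{reference_catalog}.
#' @return a \code{reference_catalog} restricted to the representatives.
#' @export
select_representatives <- function(catalog) {
  stopifnot(inherits(catalog, "reference_catalog"))
  rec <- catalog$records
  keep <- character(0)
  for (sp in unique(rec$species_key)) {
    rows <- rec[rec$species_key == sp, , drop = FALSE]
    # a strain = all records sharing (species_key, strain_label); its date is
    # the earliest date among its records
    strains <- unique(rows$strain_label)
    date_of <- vapply(strains, function(st) {
      d <- rows$release_date[rows$strain_label == st]
      if (all(is.na(d))) Inf else as.numeric(min(d, na.rm = TRUE))
    }, 0)
    if (all(!is.finite(date_of)) && length(strains) > 1L) {
      warning("no release dates for species '", sp,
              "'; falling back to lexicographic strain ordering",
              call. = FALSE)
    }
    ord <- order(date_of, strains)
    best <- strains[ord[1L]]
    keep <- c(keep, rows$record_id[rows$strain_label == best])
  }
  idx <- rec$record_id %in% keep
  structure(list(records = rec[idx, , drop = FALSE],
                 sequences = catalog$sequences[rec$record_id[idx]]),
            class = "reference_catalog")
}

#' Build the concatenated metagenomic reference
#'
#' Writes the selected genome records verbatim to a multi-record FASTA
#' (the "concatenated" reference: one FASTA record per chromosome, the
#' species rollup living in the metadata table) and a metadata TSV with one
#' row per record: \code{record_id, species_key, strain_label, length}.
#'
#' @param catalog a \code{reference_catalog} (typically the output of
#'   [select_representatives()]).
#' @param include optional character vector of species keys to keep.
#' @param exclude optional character vector of species keys to drop.
#' @param out_prefix path prefix; writes \code{<prefix>.fasta} and
#'   \code{<prefix>.meta.tsv}.
#' @return invisibly, a list with \code{fasta}, \code{meta} (paths) and the
#'   filtered \code{catalog}.
#' @export
build_reference <- function(catalog, include = NULL, exclude = NULL,
                            out_prefix) {
  stopifnot(inherits(catalog, "reference_catalog"))
  keys <- unique(catalog$records$species_key)
  for (lst in list(include = include, exclude = exclude)) {
    unknown <- setdiff(lst, keys)
    if (length(unknown)) {
      warning("species keys not in catalog: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  keep <- keys
  if (!is.null(include)) keep <- intersect(keep, include)
  if (!is.null(exclude)) keep <- setdiff(keep, exclude)
  idx <- catalog$records$species_key %in% keep
  if (!any(idx)) stop("empty selection: no species left after filtering")
  out <- structure(
    list(records = catalog$records[idx, , drop = FALSE],
         sequences = catalog$sequences[catalog$records$record_id[idx]]),
    class = "reference_catalog"
  )
  fasta <- paste0(out_prefix, ".fasta")
  meta <- paste0(out_prefix, ".meta.tsv")
  Biostrings::writeXStringSet(out$sequences, fasta)
  utils::write.table(
    out$records[, c("record_id", "species_key", "strain_label", "length")],
    meta, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(list(fasta = fasta, meta = meta, catalog = out))
}

#' Read a reference metadata table
#'
#' @param path metadata TSV written by [build_reference()] (columns
#'   \code{record_id, species_key, ...}).
#' @return data.frame.
#' @export
read_reference_meta <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
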