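#' Coverage profile of read placements on one reference record
#'
#' Bins the 0-based start positions of the reads mapped to a single record
#' into fixed-width windows. A genuinely present genome receives reads
#' spread across its whole length; reads piling into a few bins suggest a
#' shared locus (genomic island, low-complexity region) rather than
#' presence.
#'
#' @param starts integer vector of 0-based start positions on the record.
#' @param record_length record length L in bp.
#' @param read_length read length l in bp.
#' @param bin_size bin width in bp (default 10000).
#' @param record_id optional record identifier carried in the result.
#' @return object of class \code{coverage_profile}: list with fields
#'   \code{record_id, record_length, read_length, n_reads, starts}
#'   (sorted), \code{bin_size, bin_counts, occupied_bins}.
#' @export
coverage_profile <- function(starts, record_length, read_length,
                             bin_size = 10000L, record_id = NA_character_) {
  stopifnot(record_length >= 1, read_length >= 1, bin_size >= 1)
  starts <- sort(as.integer(starts))
  if (length(starts) && (min(starts) < 0 ||
                         max(starts) + read_length > record_length)) {
    stop("start positions outside the record")
  }
  n_bins <- as.integer(ceiling(record_length / bin_size))
  bin_counts <- tabulate(starts %/% bin_size + 1L, nbins = n_bins)
  structure(list(
    record_id = record_id,
    record_length = as.integer(record_length),
    read_length = as.integer(read_length),
    n_reads = length(starts),
    starts = starts,
    bin_size = as.integer(bin_size),
    bin_counts = bin_counts,
    occupied_bins = sum(bin_counts > 0L)
  ), class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf(
    "coverage_profile %s: %d reads on %d bp; %d/%d bins occupied\n",
    x$record_id, x$n_reads, x$record_length, x$occupied_bins,
    length(x$bin_counts)
  ))
  invisible(x)
}

#' Probability that n uniformly placed reads do not overlap
#'
#' Under the null model of read placement — n reads of length l with
#' independent start positions uniform over the s = L - l + 1 valid starts
#' of a sequence of length L — this is the exact probability that no two
#' reads overlap. Ordered non-overlapping placements are counted by a
#' stars-and-bars argument: choosing n starts pairwise at least l apart is
#' equivalent to choosing n distinct values in 1..(L - n*l + n), giving
#'
#'   p = n! * choose(L - n*l + n, n) / s^n
#'
#' evaluated in log space so large n and L are exact to double precision.
#' A small p for the observed (n, l, L) means at least one overlap is
#' expected by chance; conversely, observing far more overlap than this
#' null allows signals reads clustered at a restricted locus.
#'
#' @param n number of mapped reads (>= 0).
#' @param l read length in bp (1 <= l <= L).
#' @param L sequence length in bp.
#' @return probability in [0, 1]; 1 when n <= 1, 0 when n*l > L.
#' @export
no_overlap_pvalue <- function(n, l, L) {
  stopifnot(n >= 0, l >= 1)
  if (l > L) stop("read length l exceeds sequence length L")
  if (n <= 1) return(1)
  if (n * l > L) return(0)  # pigeonhole: some pair must overlap
  s <- L - l + 1
  # n! * choose(m, n) / s^n with m = L - n*l + n, evaluated as a product of
  # per-factor ratios (each <= 1) in log space: numerically exact to ~n eps
  m <- L - n * l + n
  exp(sum(log((m - seq_len(n) + 1) / s)))
}

#' Estimate feature length and abundance from mapped read counts
#'
#' With reads placed uniformly at rate \code{density_hat} (mapped reads per
#' valid start position, estimated genome-wide as n_mapped / (G - l + 1)),
#' the expected number of reads overlapping a feature of length L_f is
#' density * (L_f + l - 1): any read starting in the window of L_f + l - 1
#' positions around the feature touches it. Inverting the expectation
#' yields the length estimate
#'
#'   length_hat = n_feature / density_hat - l + 1   (floored at 0)
#'
#' and the feature's read density (reads per available start position,
#' proportional to its copy number in the community) is
#'
#'   abundance_hat = n_feature / (feature_length + l - 1)
#'
#' computed against the known feature length when one is supplied, else
#' against \code{length_hat}. About 100 mapped reads make \code{length_hat}
#' accurate to roughly 20% (relative error ~ 2/sqrt(n)), which motivates
#' the default 100-read detection threshold.
#'
#' @param n_feature reads mapped to the feature (>= 0).
#' @param read_length read length l in bp.
#' @param density_hat genome-wide reads per valid start position (> 0).
#' @param feature_length optional known feature length in bp, used for the
#'   abundance denominator.
#' @return object of class \code{feature_estimate}: list with
#'   \code{n_feature, length_hat} (NA when n_feature = 0) and
#'   \code{abundance_hat} (0 when n_feature = 0).
#' @export
estimate_feature_metrics <- function(n_feature, read_length, density_hat,
                                     feature_length = NULL) {
  stopifnot(n_feature >= 0, read_length >= 1)
  if (density_hat <= 0) stop("density_hat must be > 0")
  if (n_feature == 0) {
    return(structure(list(n_feature = 0L, length_hat = NA_real_,
                          abundance_hat = 0),
                     class = "feature_estimate"))
  }
  length_hat <- max(0, n_feature / density_hat - read_length + 1)
  denom_len <- if (!is.null(feature_length)) feature_length else length_hat
  abundance_hat <- n_feature / (denom_len + read_length - 1)
  structure(list(n_feature = as.integer(n_feature),
                 length_hat = length_hat,
                 abundance_hat = abundance_hat),
            class = "feature_estimate")
}

# observed number of overlapping read pairs (an overlap is |x_i - x_j| < l
# on the reference interval); for sorted starts, the pairs overlapping read
# i from the right are those with start <= start_i + l - 1
count_overlapping_pairs <- function(starts, l) {
  starts <- sort(starts)
  n <- length(starts)
  if (n < 2) return(0)
  sum(findInterval(starts + l - 1, starts) - seq_len(n))
}

#' Flag species whose reads concentrate at restricted loci
#'
#' Reads of a truly present genome spread across its length; hits confined
#' to a small region (a shared genomic island, a low-complexity locus) are
#' likely false positives. Two criteria are checked against the uniform
#' null:
#' \itemize{
#'   \item \strong{bin occupancy}: the observed number of occupied bins is
#'     compared with its Poisson-model expectation
#'     \eqn{B (1 - exp(-n/B))} for B bins; a ratio below
#'     \code{min_occupied_fraction} fires \code{"occupancy_deficit"}.
#'   \item \strong{overlap excess}: the observed count of overlapping read
#'     pairs is tested against its null expectation
#'     \eqn{C(n,2) (1 - p_2)} (with \eqn{p_2} the two-read no-overlap
#'     probability) using a Poisson upper tail at level
#'     \code{overlap_alpha}; an excess fires \code{"overlap_excess"}.
#' }
#'
#' @param profile a \code{coverage_profile} with \code{n_reads >= 1}.
#' @param min_occupied_fraction occupancy-ratio threshold (default 0.2).
#' @param overlap_alpha significance level for the overlap test
#'   (default 0.01).
#' @return list with \code{flag} (logical) and \code{reasons} (character
#'   vector naming the criteria that fired, empty when clean).
#' @export
flag_localized <- function(profile, min_occupied_fraction = 0.2,
                           overlap_alpha = 0.01) {
  stopifnot(inherits(profile, "coverage_profile"), profile$n_reads >= 1)
  reasons <- character(0)

  n <- profile$n_reads
  B <- length(profile$bin_counts)
  expected_occ <- B * (1 - exp(-n / B))
  if (profile$occupied_bins / expected_occ < min_occupied_fraction) {
    reasons <- c(reasons, "occupancy_deficit")
  }

  if (n >= 2) {
    p2 <- no_overlap_pvalue(2, profile$read_length, profile$record_length)
    expected_pairs <- choose(n, 2) * (1 - p2)
    obs_pairs <- count_overlapping_pairs(profile$starts,
                                         profile$read_length)
    tail_p <- stats::ppois(obs_pairs - 1, expected_pairs,
                           lower.tail = FALSE)
    if (tail_p < overlap_alpha && obs_pairs > expected_pairs) {
      reasons <- c(reasons, "overlap_excess")
    }
  }

  list(flag = length(reasons) > 0, reasons = reasons)
}

#' Per-record coverage report across a whole run
#'
#' Convenience wrapper building one [coverage_profile()] per reference
#' record with mapped reads, computing the no-overlap probability and the
#' localized-hits flag for each.
#'
#' @param alignments an \code{alignment_frame}.
#' @param metadata record_id to species_key table with a \code{length}
#'   column.
#' @param read_length read length in bp.
#' @param bin_size bin width (default 10000).
#' @param min_occupied_fraction,overlap_alpha thresholds passed to
#'   [flag_localized()].
#' @return data.frame with one row per record carrying reads:
#'   \code{species_key, record_id, n_reads, occupied_bins, expected_bins,
#'   p_no_overlap, flag, reasons}.
#' @export
coverage_report <- function(alignments, metadata, read_length,
                            bin_size = 10000L,
                            min_occupied_fraction = 0.2,
                            overlap_alpha = 0.01) {
  stopifnot(all(c("record_id", "species_key", "length") %in%
                  names(metadata)))
  mapped <- alignments[alignments$mapped, , drop = FALSE]
  rids <- unique(mapped$record_id)
  rows <- lapply(rids, function(rid) {
    L <- metadata$length[match(rid, metadata$record_id)]
    starts <- mapped$start[mapped$record_id == rid]
    prof <- coverage_profile(starts, L, read_length, bin_size, rid)
    fl <- flag_localized(prof, min_occupied_fraction, overlap_alpha)
    B <- length(prof$bin_counts)
    data.frame(
      species_key = metadata$species_key[match(rid, metadata$record_id)],
      record_id = rid,
      n_reads = prof$n_reads,
      occupied_bins = prof$occupied_bins,
      expected_bins = B * (1 - exp(-prof$n_reads / B)),
      p_no_overlap = no_overlap_pvalue(prof$n_reads, read_length, L),
      flag = fl$flag,
      reasons = paste(fl$reasons, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(species_key = character(0), record_id = character(0),
                      n_reads = integer(0), occupied_bins = integer(0),
                      expected_bins = numeric(0), p_no_overlap = numeric(0),
                      flag = logical(0), reasons = character(0))
  }
  out[order(-out$n_reads), , drop = FALSE]
}
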