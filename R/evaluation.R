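#' Score detected species against the simulation truth
#'
#' Straight set arithmetic over species keys, with reference-awareness: a
#' false negative whose species is absent from the reference could never
#' have been detected by a closed-reference method, so it is reported
#' separately in \code{fn_absent_from_reference}.
#'
#' @param truth character vector of species keys present in the community.
#' @param detected character vector of species keys reported present.
#' @param reference_species character vector of species keys present in
#'   the reference.
#' @return object of class \code{detection_report}: list with the sets
#'   \code{truth_species, detected_species, reference_species,
#'   true_positives, false_positives, false_negatives,
#'   fn_absent_from_reference} and the fractions \code{recall, precision}.
#' @export
evaluate_detection <- function(truth, detected, reference_species) {
  truth <- unique(as.character(truth))
  detected <- unique(as.character(detected))
  reference_species <- unique(as.character(reference_species))
  tp <- intersect(truth, detected)
  fp <- setdiff(detected, truth)
  fn <- setdiff(truth, detected)
  structure(list(
    truth_species = truth,
    detected_species = detected,
    reference_species = reference_species,
    true_positives = tp,
    false_positives = fp,
    false_negatives = fn,
    fn_absent_from_reference = setdiff(fn, reference_species),
    recall = if (length(truth)) length(tp) / length(truth) else 1,
    precision = if (length(detected)) length(tp) / length(detected) else 1
  ), class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    paste0("detection_report: %d truth, %d detected; TP %d, FP %d, FN %d",
           " (%d absent from reference)\nrecall %.3f  precision %.3f\n"),
    length(x$truth_species), length(x$detected_species),
    length(x$true_positives), length(x$false_positives),
    length(x$false_negatives), length(x$fn_absent_from_reference),
    x$recall, x$precision
  ))
  invisible(x)
}

#' Write a detection report as TSV
#'
#' One row per species in truth or detected, with its status, plus a
#' trailing summary block in header comments.
#'
#' @param report a \code{detection_report}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_detection_report <- function(report, path) {
  all_sp <- sort(union(report$truth_species, report$detected_species))
  df <- data.frame(
    species_key = all_sp,
    in_truth = all_sp %in% report$truth_species,
    detected = all_sp %in% report$detected_species,
    in_reference = all_sp %in% report$reference_species,
    status = ifelse(all_sp %in% report$true_positives, "TP",
                    ifelse(all_sp %in% report$false_positives, "FP", "FN")),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  writeLines(sprintf("# recall=%.6f precision=%.6f fn_absent_from_reference=%d",
                     report$recall, report$precision,
                     length(report$fn_absent_from_reference)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Per-species read-assignment accuracy
#'
#' For each species in the truth table, the fraction of its inserted reads
#' that the classifier assigned to the correct species; unassigned reads
#' (unmapped, or mapped to no species) count as incorrect. The summary is
#' the unweighted mean over truth species, so rare and abundant community
#' members contribute equally.
#'
#' @param truth data.frame with \code{read_id, species_key} covering every
#'   read.
#' @param assigned data.frame with \code{read_id, species_key}
#'   (NA = unassigned); every assigned read must appear in the truth.
#' @return list with \code{per_species} (data.frame: species_key,
#'   n_inserted, n_correct, fraction_correct) and \code{mean_accuracy}.
#' @export
assignment_accuracy <- function(truth, assigned) {
  stopifnot(all(c("read_id", "species_key") %in% names(truth)),
            all(c("read_id", "species_key") %in% names(assigned)))
  extra <- setdiff(assigned$read_id, truth$read_id)
  if (length(extra)) {
    stop("assigned read(s) absent from truth: ",
         paste(utils::head(extra, 5L), collapse = ", "),
         if (length(extra) > 5L) ", ...")
  }
  call <- assigned$species_key[match(truth$read_id, assigned$read_id)]
  correct <- !is.na(call) & call == truth$species_key
  per <- do.call(rbind, lapply(split(correct, truth$species_key),
                               function(v) {
    data.frame(n_inserted = length(v), n_correct = sum(v))
  }))
  per <- data.frame(species_key = rownames(per), per,
                    row.names = NULL, stringsAsFactors = FALSE)
  per$fraction_correct <- per$n_correct / per$n_inserted
  list(per_species = per,
       mean_accuracy = mean(per$fraction_correct))
}
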