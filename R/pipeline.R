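#' Parse a flat key: value run-configuration file
#'
#' The configuration format is a flat "key: value" document (one pair per
#' line, '#' comments allowed). Recognised keys mirror [run_pipeline()]'s
#' arguments; unknown keys are an error so typos cannot silently fall back
#' to defaults.
#'
#' @param path config file path.
#' @return named list of configuration values (strings; coerced by
#'   [run_pipeline()]).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$",
                                  lines))
  bad <- lines[lengths(kv) == 0L]
  if (length(bad)) stop("malformed config line(s): ",
                        paste(bad, collapse = "; "))
  out <- stats::setNames(
    lapply(kv, function(m) trimws(m[3L])),
    vapply(kv, `[[`, "", 2L)
  )
  known <- c("reference_fasta", "reference_meta", "reads", "truth",
             "out_dir", "aligner", "max_mismatches", "min_reads",
             "read_length", "trim_length", "trim_offset", "bin_size",
             "seed", "external_template", "external_extra")
  unknown <- setdiff(names(out), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  out
}

#' Run the full attribution pipeline
#'
#' Orchestrates: load reference, load (and optionally trim) reads, align
#' (built-in or external), roll counts up to species, apply the detection
#' threshold, build the coverage report, and — when truth labels are
#' supplied — score detection and read assignment. Every run writes a
#' machine-readable \code{manifest.json} (parameters, seed, package
#' version, input checksums) and a \code{run.log}; all tables reference the
#' manifest in a header comment, and re-running with an identical
#' configuration reproduces identical tables.
#'
#' @param config named list as produced by [read_run_config()], or a path
#'   to a config file. Required keys: \code{reference_fasta},
#'   \code{reference_meta}, \code{reads}, \code{out_dir}. Optional:
#'   \code{truth} (truth TSV), \code{aligner} ("builtin", default),
#'   \code{max_mismatches} (3), \code{min_reads} (100), \code{trim_length}
#'   + \code{trim_offset}, \code{bin_size} (10000),
#'   \code{external_template}/\code{external_extra} for an external
#'   aligner.
#' @return invisibly, a list with the output directory, the species count
#'   table, detected species, the coverage report and (if truth was given)
#'   the evaluation results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  need <- c("reference_fasta", "reference_meta", "reads", "out_dir")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop("config missing required key(s): ",
         paste(missing, collapse = ", "))
  }
  for (key in c("reference_fasta", "reference_meta", "reads")) {
    if (!file.exists(config[[key]])) {
      stop("config ", key, " does not exist: ", config[[key]])
    }
  }
  num <- function(key, default) {
    if (is.null(config[[key]])) default else as.numeric(config[[key]])
  }
  aligner <- if (is.null(config$aligner)) "builtin" else config$aligner
  k <- as.integer(num("max_mismatches", 3))
  min_reads <- as.integer(num("min_reads", 100))
  bin_size <- as.integer(num("bin_size", 10000))

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, ...) {
    cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                stage, sprintf(...)), file = log_path, append = TRUE)
  }
  stage <- "setup"
  result <- tryCatch({
    stage <- "load_reference"
    catalog <- load_reference(config$reference_fasta, config$reference_meta)
    meta <- catalog$records
    logf(stage, "%d records, %d species", nrow(meta),
         length(unique(meta$species_key)))

    stage <- "load_reads"
    reads <- read_reads(config$reads,
                        truth_path = config$truth)
    logf(stage, "%d reads", length(reads))

    if (!is.null(config$trim_length)) {
      stage <- "trim"
      reads <- trim_reads(reads, as.integer(config$trim_length),
                          as.integer(num("trim_offset", 0)))
      logf(stage, "%d reads retained, %d dropped", length(reads),
           attr(reads, "dropped"))
    }

    stage <- "align"
    if (aligner == "builtin") {
      aln <- builtin_align(reads, catalog, max_mismatches = k)
      write_sam(aln, reads, catalog,
                file.path(out_dir, "alignments.sam"))
    } else if (aligner == "external") {
      sam <- invoke_external_aligner(
        config$reads, config$reference_fasta,
        file.path(out_dir, "alignments.sam"),
        template = config$external_template,
        extra = if (is.null(config$external_extra)) "" else
          config$external_extra
      )
      aln <- read_alignments(sam)
    } else {
      stop("unknown aligner: ", aligner)
    }
    logf(stage, "%d/%d reads mapped", sum(aln$mapped), nrow(aln))

    stage <- "attribute"
    tab <- count_by_species(aln, meta)
    detected <- detect_species(tab, min_reads = min_reads)
    write_species_table(tab, file.path(out_dir, "counts"),
                        manifest = "manifest.json")
    writeLines(detected, file.path(out_dir, "detected_species.txt"))
    logf(stage, "%d species rows, %d detected at threshold %d",
         nrow(tab), length(detected), min_reads)

    stage <- "coverage"
    read_length <- min(Biostrings::width(reads$sequences))
    cov <- coverage_report(aln, meta, read_length, bin_size = bin_size)
    con <- file(file.path(out_dir, "coverage_report.tsv"), "w")
    writeLines("# manifest: manifest.json", con)
    utils::write.table(cov, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    logf(stage, "%d records profiled, %d flagged", nrow(cov),
         sum(cov$flag))

    evalr <- NULL
    if (!is.null(reads$truth)) {
      stage <- "evaluate"
      det_rep <- evaluate_detection(unique(reads$truth$species_key),
                                    detected,
                                    unique(meta$species_key))
      acc <- assignment_accuracy(
        reads$truth[, c("read_id", "species_key")],
        assign_reads(aln, meta)
      )
      write_detection_report(det_rep,
                             file.path(out_dir, "detection_report.tsv"))
      con <- file(file.path(out_dir, "assignment_accuracy.tsv"), "w")
      writeLines(c("# manifest: manifest.json",
                   sprintf("# mean_accuracy=%.6f", acc$mean_accuracy)), con)
      utils::write.table(acc$per_species, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
      evalr <- list(detection = det_rep, accuracy = acc)
      logf(stage, "recall %.3f precision %.3f mean accuracy %.3f",
           det_rep$recall, det_rep$precision, acc$mean_accuracy)
    }

    stage <- "manifest"
    manifest <- list(
      package = "metashot",
      version = as.character(utils::packageVersion("metashot")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      parameters = list(aligner = aligner, max_mismatches = k,
                        min_reads = min_reads, bin_size = bin_size,
                        trim_length = config$trim_length,
                        trim_offset = config$trim_offset,
                        seed = config$seed),
      inputs = lapply(
        stats::setNames(
          c(config$reference_fasta, config$reference_meta, config$reads),
          c("reference_fasta", "reference_meta", "reads")
        ),
        function(p) list(path = p, md5 = unname(tools::md5sum(p)))
      )
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    list(out_dir = out_dir, species_table = tab, detected = detected,
         coverage = cov, evaluation = evalr)
  }, error = function(e) {
    logf(stage, "ERROR: %s", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}

# Accepts either a raw genome-collection metadata table (record_id,
# organism_name, ...) or the reference metadata written by build_reference()
# (record_id, species_key, ...).
load_reference <- function(fasta, meta_path) {
  md <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#")
  if ("species_key" %in% names(md)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    md <- md[match(names(seqs), md$record_id), , drop = FALSE]
    if (anyNA(md$record_id)) stop("reference metadata does not cover FASTA")
    records <- data.frame(
      record_id = md$record_id,
      organism_name = paste(md$species_key, md$strain_label),
      species_key = md$species_key,
      strain_label = if ("strain_label" %in% names(md)) md$strain_label
                     else "",
      release_date = as.Date(rep(NA_character_, nrow(md))),
      length = Biostrings::width(seqs),
      stringsAsFactors = FALSE
    )
    structure(list(records = records, sequences = seqs),
              class = "reference_catalog")
  } else {
    read_genomes(fasta, meta_path)
  }
}

#' Generate a self-contained synthetic fixture set
#'
#' Writes a small mock community to disk: synthetic genomes (FASTA +
#' metadata TSV), simulated reads (FASTA + truth TSV), a community-design
#' TSV and a ready-to-run pipeline config. Intended for tests, demos and
#' smoke runs.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_species number of genomes (default 3).
#' @param genome_length genome length in bp (default 50000).
#' @param reads_per_species reads simulated per species (default 1000).
#' @param read_length read length (default 50).
#' @param sub_rate substitution rate (default 0.01).
#' @return invisibly, named vector of the paths written.
#' @export
make_fixtures <- function(out_dir, seed, n_species = 3L,
                          genome_length = 50000L,
                          reads_per_species = 1000L, read_length = 50L,
                          sub_rate = 0.01) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  catalog <- simulate_genomes(n_species, genome_length, seed = seed)
  design <- data.frame(id = catalog$records$record_id,
                       read_count = reads_per_species)
  reads <- simulate_reads(catalog, design, read_length = read_length,
                          sub_rate = sub_rate, seed = seed + 1L)
  paths <- c(
    genomes = file.path(out_dir, "genomes.fasta"),
    genome_meta = file.path(out_dir, "genomes.meta.tsv"),
    reads = file.path(out_dir, "reads.fasta"),
    truth = file.path(out_dir, "truth.tsv"),
    design = file.path(out_dir, "design.tsv"),
    config = file.path(out_dir, "run.config")
  )
  Biostrings::writeXStringSet(catalog$sequences, paths[["genomes"]])
  utils::write.table(
    data.frame(record_id = catalog$records$record_id,
               organism_name = catalog$records$organism_name,
               strain = catalog$records$strain_label,
               date = NA),
    paths[["genome_meta"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_reads(reads, paths[["reads"]], truth_path = paths[["truth"]])
  utils::write.table(design, paths[["design"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c(
    paste0("reference_fasta: ", paths[["genomes"]]),
    paste0("reference_meta: ", paths[["genome_meta"]]),
    paste0("reads: ", paths[["reads"]]),
    paste0("truth: ", paths[["truth"]]),
    paste0("out_dir: ", file.path(out_dir, "run")),
    "aligner: builtin",
    "max_mismatches: 3",
    "min_reads: 100",
    paste0("seed: ", seed)
  ), paths[["config"]])
  invisible(paths)
}
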