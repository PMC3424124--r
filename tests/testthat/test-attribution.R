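meta3 <- data.frame(
  record_id = c("chrA1", "chrA2", "chrB1"),
  species_key = c("Examplea prima", "Examplea prima", "Examplea secunda"),
  stringsAsFactors = FALSE
)

test_that("counts roll up chromosomes into one species row", {
  a <- aln_frame(sprintf("r%d", 1:6),
                 c("chrA1", "chrA1", "chrA1", "chrA2", "chrA2", NA))
  tab <- count_by_species(a, meta3)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$species_key, "Examplea prima")
  expect_equal(tab$read_count, 5L)
  expect_equal(attr(tab, "total_reads"), 6L)
  expect_equal(attr(tab, "mapped_reads"), 5L)
  expect_equal(attr(tab, "unmapped_reads"), 1L)
  expect_equal(tab$fraction_of_total, 5 / 6)
  # per-record sub-table preserves the chromosome split
  rc <- attr(tab, "record_counts")
  expect_setequal(rc$record_id, c("chrA1", "chrA2"))
  expect_equal(sort(rc$read_count), c(2L, 3L))
})

test_that("empty streams and unknown records are handled", {
  empty <- aln_frame(character(0), character(0))
  tab <- count_by_species(empty, meta3)
  expect_equal(nrow(tab), 0L)
  expect_equal(attr(tab, "total_reads"), 0L)
  expect_error(
    count_by_species(aln_frame("r1", "chrZZ"), meta3),
    "chrZZ"
  )
})

test_that("two strains sharing a species key are summed in one row", {
  meta <- data.frame(
    record_id = c("halo_R1", "halo_NRC1"),
    species_key = rep("Halobacterium salinarum", 2),
    stringsAsFactors = FALSE
  )
  # reads split roughly half/half between near-identical strains
  a <- aln_frame(sprintf("r%d", 1:10),
                 rep(c("halo_R1", "halo_NRC1"), each = 5))
  tab <- count_by_species(a, meta)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$read_count, 10L)
  expect_equal(nrow(attr(tab, "record_counts")), 2L)
})

test_that("count conservation holds on random attribution tables", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    recs <- sample(c(meta3$record_id, NA), n, replace = TRUE)
    a <- aln_frame(sprintf("r%d", seq_len(n)), recs)
    tab <- count_by_species(a, meta3)
    expect_equal(sum(tab$read_count), attr(tab, "mapped_reads"))
    expect_equal(attr(tab, "mapped_reads") + attr(tab, "unmapped_reads"),
                 attr(tab, "total_reads"))
    expect_equal(attr(tab, "total_reads"), n)
    expect_equal(sum(attr(tab, "record_counts")$read_count),
                 attr(tab, "mapped_reads"))
  }
})

test_that("detection threshold is inclusive and monotone", {
  a <- aln_frame(sprintf("r%d", 1:199),
                 c(rep("chrA1", 100), rep("chrB1", 99)))
  tab <- count_by_species(a, meta3)
  expect_equal(detect_species(tab, 100), "Examplea prima")   # 100 >= 100
  expect_false("Examplea secunda" %in% detect_species(tab, 100))  # 99 < 100
  expect_setequal(detect_species(tab, 0),
                  c("Examplea prima", "Examplea secunda"))
  # monotonicity: raising the threshold never adds a species
  set.seed(62)
  recs <- sample(meta3$record_id, 500, replace = TRUE)
  tab2 <- count_by_species(aln_frame(sprintf("r%d", 1:500), recs), meta3)
  prev <- detect_species(tab2, 0)
  for (thr in c(1, 50, 100, 150, 200, 1000)) {
    cur <- detect_species(tab2, thr)
    expect_true(all(cur %in% prev), info = paste("threshold", thr))
    prev <- cur
  }
})

test_that("detected species are ordered by count then key", {
  a <- aln_frame(sprintf("r%d", 1:9),
                 c(rep("chrA1", 3), rep("chrB1", 3), rep("chrA2", 3)))
  tab <- count_by_species(a, meta3)
  # Examplea prima has 6, secunda 3
  expect_equal(detect_species(tab, 1),
               c("Examplea prima", "Examplea secunda"))
})

test_that("decoy filtering removes exactly the host-derived reads", {
  host <- simulate_genomes(1, 5000, seed = 71,
                           species_names = "Homo sapiens")
  bact <- random_catalog(n_rec = 1, len = 5000, seed = 72)
  host_reads <- simulate_reads(host, data.frame(id = host$records$record_id,
                                                read_count = 40L),
                               read_length = 50, sub_rate = 0, seed = 73)
  bact_reads <- simulate_reads(bact, data.frame(id = "rec01",
                                                read_count = 60L),
                               read_length = 50, sub_rate = 0, seed = 74)
  mixed <- read_set(
    c(host_reads$sequences, bact_reads$sequences),
    rbind(host_reads$truth, bact_reads$truth)
  )
  decoy_aln <- builtin_align(mixed, host, max_mismatches = 0)
  parts <- filter_reads_by_reference(mixed, decoy_aln)
  expect_equal(length(parts$removed), 40L)
  expect_equal(length(parts$retained), 60L)
  # exact partition
  expect_setequal(c(names(parts$retained$sequences),
                    names(parts$removed$sequences)),
                  names(mixed$sequences))
  # truth labels of the removed set are exactly the host reads
  expect_true(all(parts$removed$truth$species_key == "Homo sapiens"))
  expect_true(all(parts$retained$truth$species_key != "Homo sapiens"))
})

test_that("decoy filtering degenerate cases and stray ids", {
  rs <- read_set(Biostrings::DNAStringSet(c(a = "ACGT", b = "GGGG")))
  none <- aln_frame(c("a", "b"), c(NA, NA))
  p1 <- filter_reads_by_reference(rs, none)
  expect_equal(length(p1$retained), 2L)
  expect_equal(length(p1$removed), 0L)
  all_hit <- aln_frame(c("a", "b"), c("decoy", "decoy"))
  p2 <- filter_reads_by_reference(rs, all_hit)
  expect_equal(length(p2$retained), 0L)
  expect_warning(
    filter_reads_by_reference(rs, aln_frame("zz", "decoy")),
    "absent from the read set"
  )
})

test_that("species tables export with totals and manifest header", {
  a <- aln_frame(sprintf("r%d", 1:5),
                 c("chrA1", "chrA1", "chrB1", "chrB1", NA))
  tab <- count_by_species(a, meta3)
  prefix <- file.path(withr::local_tempdir(), "counts")
  paths <- write_species_table(tab, prefix, manifest = "manifest.json")
  lines <- readLines(paths[["species"]])
  expect_true(any(grepl("manifest.json", lines)))
  back <- utils::read.delim(paths[["species"]], comment.char = "#")
  expect_equal(sum(back$read_count), 4L)
})
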