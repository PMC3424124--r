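test_that("organism names parse to species key + strain label", {
  cases <- list(
    list("Halobacterium salinarum R1", "Halobacterium salinarum", "R1"),
    list("Marinomonas sp. MWYL1", "Marinomonas sp. MWYL1", ""),
    list("Candidatus Pelagibacter ubique HTCC1062",
         "Candidatus Pelagibacter ubique", "HTCC1062"),
    list("Shewanella loihica PV-4", "Shewanella loihica", "PV-4"),
    list("Rhodopseudomonas palustris CGA009",
         "Rhodopseudomonas palustris", "CGA009"),
    list("Escherichia coli K-12 MG1655", "Escherichia coli",
         "K-12 MG1655")
  )
  for (cs in cases) {
    p <- parse_organism_name(cs[[1]])
    expect_equal(p$species_key, cs[[2]], info = cs[[1]])
    expect_equal(p$strain_label, cs[[3]], info = cs[[1]])
  }
})

test_that("single-token descriptions warn but still yield a key", {
  expect_warning(p <- parse_organism_name("Synechococcus"),
                 "single-token")
  expect_equal(p$species_key, "Synechococcus")
  expect_equal(p$strain_label, "")
})

test_that("parse_organism_name is total on printable input", {
  set.seed(11)
  pool <- c(LETTERS, letters, "sp.", ".", "-", "_", "123", "Candidatus")
  for (i in 1:50) {
    toks <- sample(pool, sample(1:6, 1), replace = TRUE)
    desc <- paste(toks, collapse = " ")
    expect_no_error(suppressWarnings(parse_organism_name(desc)))
    p <- suppressWarnings(parse_organism_name(desc))
    expect_true(nzchar(p$species_key))
  }
})

strain_catalog <- function(dates) {
  # three strains of one species, one record each
  seqs <- Biostrings::DNAStringSet(c(
    r1 = strrep("ACGT", 10), r2 = strrep("ACGT", 11),
    r3 = strrep("ACGT", 12)
  ))
  reference_catalog(seqs, data.frame(
    record_id = c("r1", "r2", "r3"),
    organism_name = paste("Rhodopseudomonas palustris",
                          c("CGA009", "BisB18", "HaA2")),
    strain = c("CGA009", "BisB18", "HaA2"),
    date = dates, stringsAsFactors = FALSE
  ))
}

test_that("earliest released strain is selected as representative", {
  cat <- strain_catalog(c("2004-01-09", "2006-03-01", "2006-01-15"))
  sel <- select_representatives(cat)
  expect_equal(sel$records$strain_label, "CGA009")
  # single-strain species passes through unchanged
  tc <- tiny_catalog()
  sel2 <- select_representatives(tc)
  expect_setequal(sel2$records$record_id, tc$records$record_id)
})

test_that("date ties and missing dates resolve deterministically", {
  # equal dates: lexicographically smaller strain label wins
  cat <- strain_catalog(c("2005-01-01", "2005-01-01", "2005-01-01"))
  expect_equal(select_representatives(cat)$records$strain_label, "BisB18")
  # strain lacking a date sorts last
  cat2 <- strain_catalog(c(NA, "2006-03-01", "2006-01-15"))
  expect_equal(select_representatives(cat2)$records$strain_label, "HaA2")
  # all dates missing: lexicographic fallback with warning
  cat3 <- strain_catalog(c(NA, NA, NA))
  expect_warning(sel3 <- select_representatives(cat3), "lexicographic")
  expect_equal(sel3$records$strain_label, "BisB18")
})

test_that("representative selection keeps whole strains and is idempotent", {
  # one strain with two chromosomes plus a later rival strain
  seqs <- Biostrings::DNAStringSet(c(a1 = strrep("ACGT", 10),
                                     a2 = strrep("TTTT", 10),
                                     b1 = strrep("GGGG", 10)))
  cat <- reference_catalog(seqs, data.frame(
    record_id = c("a1", "a2", "b1"),
    organism_name = c("Examplea prima S1", "Examplea prima S1",
                      "Examplea prima S2"),
    date = c("2001-05-05", "2001-05-05", "2003-01-01"),
    stringsAsFactors = FALSE
  ))
  sel <- select_representatives(cat)
  expect_setequal(sel$records$record_id, c("a1", "a2"))
  sel2 <- select_representatives(sel)
  expect_identical(sel$records, sel2$records)
})

test_that("build_reference writes FASTA + metadata that round-trip", {
  cat <- tiny_catalog()
  prefix <- file.path(withr::local_tempdir(), "ref")
  out <- build_reference(cat, out_prefix = prefix)
  md <- read_reference_meta(out$meta)
  expect_equal(nrow(md), 3L)
  expect_equal(length(unique(md$species_key)), 2L)
  expect_equal(md$length,
               unname(Biostrings::width(cat$sequences[md$record_id])))
  back <- Biostrings::readDNAStringSet(out$fasta)
  expect_equal(as.character(back), as.character(cat$sequences))
})

test_that("include/exclude filter species from both outputs", {
  cat <- tiny_catalog()
  prefix <- file.path(withr::local_tempdir(), "ref")
  out <- build_reference(cat, exclude = "Examplea prima",
                         out_prefix = prefix)
  md <- read_reference_meta(out$meta)
  expect_equal(unique(md$species_key), "Examplea secunda")
  back <- Biostrings::readDNAStringSet(out$fasta)
  expect_equal(names(back), "chrB1")
  # species count arithmetic: input species minus excluded
  expect_equal(length(unique(out$catalog$records$species_key)),
               length(unique(cat$records$species_key)) - 1L)
  # unknown keys warn; empty selection errors
  expect_warning(
    build_reference(cat, include = c("Examplea prima", "Nemo nullus"),
                    out_prefix = prefix),
    "not in catalog"
  )
  expect_error(
    suppressWarnings(build_reference(cat, include = "Nemo nullus",
                                     out_prefix = prefix)),
    "empty selection"
  )
})

test_that("read_genomes reads back what make-style outputs contain", {
  dir <- withr::local_tempdir()
  cat <- tiny_catalog()
  fa <- file.path(dir, "g.fasta")
  mt <- file.path(dir, "g.tsv")
  Biostrings::writeXStringSet(cat$sequences, fa)
  utils::write.table(
    data.frame(record_id = cat$records$record_id,
               organism_name = cat$records$organism_name,
               strain = cat$records$strain_label, date = NA),
    mt, sep = "\t", quote = FALSE, row.names = FALSE
  )
  back <- read_genomes(fa, mt)
  expect_equal(back$records$species_key, cat$records$species_key)
  expect_equal(as.character(back$sequences),
               as.character(cat$sequences))
})
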