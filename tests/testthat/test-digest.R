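test_that("read_fasta parses UniProt headers, species tags and sequences", {
  recs <- read_fasta(marker_fasta())
  expect_equal(nrow(recs), 7L)
  expect_equal(recs$accession[6], "SYNGPD1")
  expect_equal(recs$species[6], "chicken")
  expect_equal(recs$sequence[1], "MVHLTPEEKLLVVYPWTQRAAAK")
  # species map overrides the OS= field
  recs2 <- read_fasta(marker_fasta(), species_map = c(SYNGPD1 = "gallus"))
  expect_equal(recs2$species[6], "gallus")
})

test_that("read_fasta agrees with the Biostrings parser", {
  skip_if_not_installed("Biostrings")
  ref <- Biostrings::readAAStringSet(marker_fasta())
  recs <- read_fasta(marker_fasta())
  expect_equal(recs$sequence, unname(as.character(ref)))
})

test_that("read_fasta rejects malformed input with line numbers", {
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|ACC1|P1", "ACDEFG", ">sp|ACC2|P2", "ACD3FG"), bad)
  expect_error(read_fasta(bad), "line 4")
  writeLines(c("ACDEFG", ">x", "ACD"), bad)
  expect_error(read_fasta(bad), "before first header")
  writeLines(character(0), bad)
  expect_error(read_fasta(bad), "no FASTA records")
  writeLines(c(">sp|ACC1|P1", "ACDEFG", ">sp|ACC2|P2"), bad)
  expect_error(read_fasta(bad), "empty sequence")
})

test_that("cleavage_sites applies the Keil rule", {
  expect_length(cleavage_sites("AKPA"), 0)  # K before P suppressed
  expect_identical(cleavage_sites("AKAR"), 2L)   # terminal R excluded
  expect_identical(cleavage_sites("GRAKG"), c(2L, 4L))
  expect_identical(cleavage_sites("KPKA"), 3L)   # K before P suppressed
  expect_identical(cleavage_sites("AKAP"), 2L)   # K before A still cleaves
})

test_that("enumerate_peptides handles oxidation variants and the m/z window", {
  rec <- data.frame(accession = "X", species = "s", sequence = "MKGR",
                    stringsAsFactors = FALSE)
  out <- enumerate_peptides(rec, digest_params(max_missed_cleavages = 0,
                                               mz_min = 0, mz_max = 3000))
  expect_setequal(
    paste(out$sequence, out$oxidized_positions),
    c("MK ", "MK 1", "GR ")
  )
  ox <- out[out$oxidized_positions == "1", ]
  plain <- out[out$sequence == "MK" & out$oxidized_positions == "", ]
  expect_equal(ox$mz - plain$mz, 15.994915, tolerance = 1e-6)

  # missed-cleavage monotonicity and window contract
  rec2 <- data.frame(accession = "Y", species = "s",
                     sequence = random_protein(60), stringsAsFactors = FALSE)
  set.seed(3)
  n0 <- nrow(enumerate_peptides(rec2, digest_params(0, mz_min = 0,
                                                    mz_max = 1e5)))
  n2 <- nrow(enumerate_peptides(rec2, digest_params(2, mz_min = 0,
                                                    mz_max = 1e5)))
  expect_gte(n2, n0)
  win <- enumerate_peptides(rec2, digest_params(2, mz_min = 600,
                                                mz_max = 2000))
  expect_true(all(win$mz >= 600 & win$mz <= 2000))
})

test_that("oxidation combinatorics cap enumerates extremes only, with warning", {
  rec <- data.frame(accession = "Z", species = "s",
                    sequence = "MMMMMK", stringsAsFactors = FALSE)
  expect_warning(
    out <- enumerate_peptides(rec, digest_params(0, mz_min = 0,
                                                 mz_max = 5000)),
    "cap"
  )
  expect_setequal(out$oxidized_positions, c("", "1,2,3,4,5"))
})

test_that("digestion matches the brute-force substring oracle", {
  set.seed(42)
  params <- digest_params(max_missed_cleavages = 2,
                          variable_met_oxidation = FALSE,
                          mz_min = 0, mz_max = 1e6)
  for (i in 1:40) {
    seqstr <- random_protein(sample(5:30, 1))
    rec <- data.frame(accession = "T", species = "s", sequence = seqstr,
                      stringsAsFactors = FALSE)
    got <- unique(enumerate_peptides(rec, params)[, c("sequence",
                                                      "missed_cleavages")])
    want <- brute_force_digest(seqstr, 2L)
    key <- function(d) sort(paste(d$sequence, d$missed_cleavages))
    expect_identical(key(got), key(want), label = seqstr)
  }
})

test_that("panel digestion recovers the GAPDH species markers", {
  recs <- read_fasta(marker_fasta())
  tt <- digest_panel(recs)
  ck <- tt[tt$sequence == "LVSWYDNEFGYSNR", ]
  mam <- tt[tt$sequence == "LISWYDNEFGYSNR", ]
  expect_true(all(ck$missed_cleavages == 0))
  expect_equal(unique(ck$mz), 1749.787, tolerance = 2e-3 / 1750)
  expect_equal(unique(mam$mz), 1763.802, tolerance = 2e-3 / 1764)
  expect_true(all(ck$specificity == "proteotypic"))
})

test_that("specificity annotation marks shared and proteotypic peptides", {
  recs <- read_fasta(marker_fasta())
  tt <- digest_panel(recs)
  hbb <- tt[tt$sequence == "LLVVYPWTQR", ]
  expect_true(all(hbb$specificity == "shared"))
  expect_equal(unique(hbb$shared_species), "bovine,human,porcine")
  hba <- tt[tt$sequence == "VGGHAAEYGAEALER", ]
  expect_equal(unique(hba$shared_species), "bovine,human")
  # single-species panel: everything proteotypic
  solo <- digest_panel(recs[recs$species == "chicken", , drop = FALSE])
  expect_true(all(solo$specificity == "proteotypic"))
})

test_that("specificity shared sets are monotone in the panel", {
  recs <- read_fasta(marker_fasta())
  small <- digest_panel(recs[recs$species %in% c("human", "bovine"), ])
  big <- digest_panel(recs)
  m <- merge(as.data.frame(small)[, c("sequence", "shared_species")],
             as.data.frame(big)[, c("sequence", "shared_species")],
             by = "sequence", suffixes = c("_small", "_big"))
  n_small <- lengths(strsplit(m$shared_species_small, ","))
  n_big <- lengths(strsplit(m$shared_species_big, ","))
  expect_true(all(n_big >= n_small))
})

test_that("theoretical table round-trips through TSV", {
  recs <- read_fasta(marker_fasta())
  tt <- digest_panel(recs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_theoretical_table(tt, f)
  back <- read_theoretical_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tt), tolerance = 1e-12)

  # empty table -> header-only file
  empty <- annotate_specificity(tt[0, c("accession", "species", "sequence",
                                        "oxidized_positions",
                                        "missed_cleavages", "mz")])
  write_theoretical_table(empty, f)
  expect_length(readLines(f), 1L)
  expect_equal(nrow(read_theoretical_table(f)), 0L)

  # corrupt m/z rejected with row number
  write_theoretical_table(tt, f)
  lines <- readLines(f)
  fields <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  fields[6] <- "not_a_number"
  lines[3] <- paste(fields, collapse = "\t")
  writeLines(lines, f)
  expect_error(read_theoretical_table(f), "non-numeric mz at data row 2")
})
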