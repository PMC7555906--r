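pl_with <- function(ids, panel = marker_panel(), extra = numeric(0)) {
  mz <- vapply(ids, function(id) panel_center(id, panel), 0)
  exact_peaklist(c(mz, extra), sample_id = paste(ids, collapse = "+"))
}

test_that("classify rejects unpreprocessed peak lists", {
  raw <- peak_list(1000, 1, 50)
  expect_error(classify(raw), "not preprocessed")
})

test_that("refined branches map marker patterns to the documented claims", {
  cases <- list(
    list(ids = c("hbb_shared", "hba_shared"),
         want = c("yes", "human", "n/a", "none-detected")),
    list(ids = "gapdh_chicken",
         want = c("yes", "animal", "chicken", "none-detected")),
    list(ids = c("gapdh_mammal", "myo_1593"),
         want = c("yes", "animal", "bovine", "none-detected")),
    list(ids = c("gapdh_mammal", "myo_1670"),
         want = c("yes", "animal", "bovine", "none-detected")),
    list(ids = "gapdh_mammal",
         want = c("yes", "animal", "porcine", "none-detected")),
    list(ids = "myo_1593",
         want = c("yes", "animal", "inconclusive", "none-detected")),
    list(ids = "sem1",
         want = c("no", "n/a", "n/a", "semen")),
    list(ids = c("sem_1445", "sem_1555"),
         want = c("no", "n/a", "n/a", "semen")),
    list(ids = "hbb_shared",
         want = c("inconclusive", "n/a", "n/a", "none-detected")),
    list(ids = "sem_1445",   # one semen support alone is not enough
         want = c("no", "n/a", "n/a", "none-detected"))
  )
  for (cs in cases) {
    claim <- classify(pl_with(cs$ids))
    got <- c(claim$level_I_blood, claim$level_II_provenance,
             claim$level_III_species, claim$level_IV_other_biofluid)
    expect_identical(got, cs$want, label = paste(cs$ids, collapse = "+"))
  }
})

test_that("empty spectrum yields a no-blood claim", {
  claim <- classify(exact_peaklist(numeric(0)))
  expect_identical(claim$level_I_blood, "no")
  expect_identical(claim$branch, "no-blood")
})

test_that("human branch notes semen co-presence and the bovine caveat", {
  claim <- classify(pl_with(c("hbb_shared", "hba_shared", "sem1")))
  expect_identical(claim$level_II_provenance, "human")
  expect_true(any(grepl("co-presence", claim$notes)))
  expect_true(any(grepl("bovine", claim$notes)))
})

test_that("porcine nominal-649 support raises confidence without driving claims", {
  # a peak inside 649 +/- 0.5 Th plus mammal GAPDH
  claim <- classify(pl_with("gapdh_mammal", extra = 649.35))
  expect_identical(claim$level_III_species, "porcine")
  expect_true(any(grepl("649", claim$notes)))
  # the 649 window alone claims nothing
  alone <- classify(exact_peaklist(649.35))
  expect_identical(alone$level_I_blood, "no")
})

test_that("bovine_from_myoglobin_alone upgrades 1593-only and changes nothing else", {
  cfg <- strategy_config(bovine_from_myoglobin_alone = TRUE)
  up <- classify(pl_with("myo_1593"), cfg = cfg)
  expect_identical(up$level_III_species, "bovine")
  # other patterns are untouched
  for (ids in list("gapdh_chicken", c("hbb_shared", "hba_shared"),
                   "gapdh_mammal", "sem1")) {
    a <- classify(pl_with(ids))
    b <- classify(pl_with(ids), cfg = cfg)
    expect_identical(a[c("level_I_blood", "level_II_provenance",
                         "level_III_species", "level_IV_other_biofluid")],
                     b[c("level_I_blood", "level_II_provenance",
                         "level_III_species", "level_IV_other_biofluid")])
  }
})

test_that("initial strategy ignores animal and semen markers", {
  # chicken marker only: the historical false negative
  expect_identical(classify_initial(pl_with("gapdh_chicken"))$level_I_blood,
                   "no")
  expect_identical(classify_initial(pl_with("sem1"))$level_I_blood, "no")
  hu <- classify_initial(pl_with(c("hbb_shared", "hba_shared")))
  expect_identical(hu$level_II_provenance, "human")
  one <- classify_initial(pl_with("hba_shared"))
  expect_identical(one$level_I_blood, "inconclusive")
  expect_true(any(grepl("MS/MS", one$notes)))
})

test_that("claims are deterministic and exactly one branch fires", {
  pl <- pl_with(c("gapdh_mammal", "myo_1593", "sem1"))
  c1 <- classify(pl); c2 <- classify(pl)
  expect_identical(explain(c1), explain(c2))
  expect_length(c1$branch, 1L)
  expect_identical(c1$branch, "bovine")  # blood branches precede semen
})

test_that("removing peaks never turns a negative claim blood-positive", {
  set.seed(13)
  for (i in 1:15) {
    mz <- runif(8, 600, 2000)
    pl <- exact_peaklist(mz)
    base <- classify(pl)
    if (base$level_I_blood != "no") next
    for (j in seq_len(nrow(pl))) {
      sub <- exact_peaklist(pl$mz[-j])
      expect_identical(classify(sub)$level_I_blood, "no")
    }
  }
})

test_that("explain renders evidence, ppm values and narratives", {
  rep1 <- explain(classify(pl_with(c("hbb_shared", "hba_shared"))))
  expect_true(any(grepl("hbb_shared", rep1)))
  expect_true(any(grepl("ppm", rep1)))
  rep0 <- explain(classify(exact_peaklist(numeric(0))))
  expect_true(any(grepl("no blood detected", rep0)))
})

test_that("claim level invariants are enforced", {
  expect_error(bloodPMF:::new_claim("no", "human", "n/a", "none-detected",
                                    "x"),
               "level II")
  expect_error(bloodPMF:::new_claim("yes", "human", "bovine",
                                    "none-detected", "x"),
               "level III")
})
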