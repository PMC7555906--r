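test_that("default refined panel resolves the printed centers", {
  panel <- marker_panel()
  expect_equal(panel_center("hbb_shared"), 1274.725, tolerance = 2e-3 / 1274)
  expect_equal(panel_center("hba_shared"), 1529.734, tolerance = 2e-3 / 1529)
  expect_equal(panel_center("gapdh_chicken"), 1749.787,
               tolerance = 2e-3 / 1750)
  expect_equal(panel_center("gapdh_mammal"), 1763.802,
               tolerance = 2e-3 / 1764)
  expect_identical(panel_center("myo_1670"), 1669.837)  # literal passthrough
  # every sequence-backed center reproduces its nominal label
  for (m in panel$markers) {
    ctr <- resolve_center(m)
    if (!is.na(ctr)) expect_identical(nominal_mz(ctr), m$nominal)
  }
})

test_that("nominal-only markers are inactive; ids unique; initial panel is HB-only", {
  panel <- marker_panel()
  m649 <- NULL
  for (m in panel$markers) if (m$id == "myo_porcine_649") m649 <- m
  expect_false(is_active_marker(m649))
  expect_identical(m649$nominal, 649L)
  ids <- vapply(panel$markers, `[[`, "", "id")
  expect_false(anyDuplicated(ids) > 0)
  init <- marker_panel("initial")
  expect_true(all(vapply(init$markers, `[[`, "", "protein") %in%
                    c("HBB", "HBA", "EPB42", "Hpt")))
})

test_that("match_marker implements the two-stage 30/15 ppm bands", {
  panel <- marker_panel()
  hbb <- panel$markers[[1]]
  ctr <- resolve_center(hbb)

  exact <- exact_peaklist(ctr)
  r <- match_marker(exact, hbb)
  expect_identical(r$stage, "confirmed")
  expect_equal(r$ppm, 0, tolerance = 1e-9)

  r20 <- match_marker(exact_peaklist(ctr * (1 + 20e-6)), hbb)
  expect_identical(r20$stage, "candidate")

  r40 <- match_marker(exact_peaklist(ctr * (1 + 40e-6)), hbb)
  expect_identical(r40$stage, "unmatched")

  # nearest-|ppm| selection: -10 ppm beats +12 ppm
  two <- exact_peaklist(ctr * (1 + c(-10e-6, 12e-6)))
  rr <- match_marker(two, hbb)
  expect_equal(rr$ppm, -10, tolerance = 1e-6)

  # ppm ties break toward higher intensity
  tie <- peak_list(ctr * (1 + c(-5e-6, 5e-6)), c(10, 99), c(50, 50))
  tie <- preprocess_peaklist(tie, exclusion = NULL)
  rt <- match_marker(tie, hbb)
  expect_equal(rt$intensity, 99)

  expect_error(match_marker(exact, hbb, candidate_ppm = 10,
                            confirm_ppm = 15), "confirm_ppm")
})

test_that("match_panel confirms a synthetic human blood list and is total", {
  panel <- marker_panel()
  human <- exact_peaklist(c(panel_center("hbb_shared"),
                            panel_center("hba_shared")))
  res <- match_panel(human, panel)
  expect_equal(nrow(res), length(panel$markers))
  expect_identical(res$stage[res$marker_id == "hbb_shared"], "confirmed")
  expect_identical(res$stage[res$marker_id == "hba_shared"], "confirmed")

  empty <- exact_peaklist(numeric(0))
  res0 <- match_panel(empty, panel)
  expect_true(all(res0$stage == "unmatched"))
})

test_that("all active markers confirm at 0 ppm on the all-centers list", {
  panel <- marker_panel()
  centers <- vapply(panel$markers, resolve_center, 0)
  pl <- exact_peaklist(centers[!is.na(centers)])
  res <- match_panel(pl, panel)
  act <- res[res$active, ]
  expect_true(all(act$stage == "confirmed"))
  expect_equal(act$ppm, rep(0, nrow(act)), tolerance = 1e-9)
})

test_that("narrowing confirm_ppm never adds confirmed matches", {
  set.seed(5)
  panel <- marker_panel()
  centers <- vapply(panel$markers, resolve_center, 0)
  centers <- centers[!is.na(centers)]
  for (i in 1:20) {
    jit <- centers * (1 + rnorm(length(centers), 0, 8) / 1e6)
    pl <- exact_peaklist(jit)
    for (tol in c(15, 10, 5, 2)) {
      wide <- match_panel(pl, panel, confirm_ppm = tol)
      narrow <- match_panel(pl, panel, confirm_ppm = tol / 2)
      expect_true(all(narrow$marker_id[narrow$stage == "confirmed"] %in%
                        wide$marker_id[wide$stage == "confirmed"]))
    }
  }
})

test_that("present markers confirm >99% of the time at 3 ppm jitter", {
  # 15 ppm confirmation at 3 ppm jitter is a 5-sigma window
  set.seed(99)
  panel <- marker_panel()
  hbb <- panel$markers[[1]]
  ctr <- resolve_center(hbb)
  n <- 1000
  obs <- ctr * (1 + rnorm(n, 0, 3) / 1e6)
  confirmed <- vapply(obs, function(x)
    match_marker(exact_peaklist(x), hbb)$stage == "confirmed", logical(1))
  expect_gt(mean(confirmed), 0.99)
})

test_that("table annotation equals the all-pairs oracle on random instances", {
  set.seed(77)
  for (i in 1:200) {
    nt <- sample(3:25, 1)
    base <- sort(runif(nt, 600, 2000))
    tt <- annotate_specificity(data.frame(
      accession = sprintf("A%d", seq_len(nt)), species = "s",
      sequence = sprintf("PEP%d", seq_len(nt)),
      oxidized_positions = "", missed_cleavages = 0L, mz = base,
      stringsAsFactors = FALSE))
    np <- sample(1:15, 1)
    # half the peaks near table entries, half anywhere
    near <- sample(base, ceiling(np / 2), replace = TRUE) *
      (1 + rnorm(ceiling(np / 2), 0, 20) / 1e6)
    pmz <- c(near, runif(floor(np / 2), 600, 2000))
    pl <- peak_list(pmz, rep(1, length(pmz)), rep(50, length(pmz)))
    got <- annotate_against_table(pl, tt)
    want <- brute_force_annotate(pl, tt, 30, 15)
    key <- function(d) sort(sprintf("%.6f|%s|%s", d$peak_mz, d$sequence,
                                    d$stage))
    expect_identical(key(got), key(want))
  }
})

test_that("annotation flags confirmed-ambiguous isobaric entries", {
  mz0 <- 1500
  tt <- annotate_specificity(data.frame(
    accession = c("A", "B"), species = c("s1", "s2"),
    sequence = c("PEPA", "PEPB"), oxidized_positions = "",
    missed_cleavages = 0L, mz = c(mz0, mz0 * (1 + 5e-6)),
    stringsAsFactors = FALSE))
  pl <- peak_list(mz0 * (1 + 2e-6), 1, 50)
  out <- annotate_against_table(pl, tt)
  expect_equal(nrow(out), 2L)
  expect_true(all(out$ambiguous))
  expect_true(all(out$stage == "confirmed"))

  solo <- annotate_against_table(peak_list(mz0, 1, 50), tt[1, ])
  expect_equal(nrow(solo), 1L)
  expect_false(solo$ambiguous)
})
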