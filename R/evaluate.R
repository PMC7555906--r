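truth_expectation <- function(truth) {
  switch(truth,
    human_blood   = list(I = "yes", II = "human",  III = "n/a",
                         IV = "none-detected"),
    bovine_blood  = list(I = "yes", II = "animal", III = "bovine",
                         IV = "none-detected"),
    porcine_blood = list(I = "yes", II = "animal", III = "porcine",
                         IV = "none-detected"),
    chicken_blood = list(I = "yes", II = "animal", III = "chicken",
                         IV = "none-detected"),
    semen         = list(I = "no",  II = "n/a",    III = "n/a",
                         IV = "semen"),
    # saliva, sweat, non-biofluid matrices, blanks: a correct claim is
    # "not blood" with no other biofluid reported
    list(I = "no", II = "n/a", III = "n/a", IV = "none-detected")
  )
}

is_blood_truth <- function(truth) endsWith(truth, "_blood")

#' Score one claim against ground truth
#'
#' \code{full_correct}: every applicable identification level matches the
#' truth (the species level applies only to animal blood; a semen truth
#' requires the semen claim; a correct "not blood" for a non-blood,
#' non-semen matrix is fully correct). \code{partial}: correct at the
#' shallower levels but inconclusive or missing at a deeper one (e.g. animal
#' blood with species inconclusive, or a blood truth left level-I
#' inconclusive). \code{incorrect}: a blood truth claimed "no" (false
#' negative), a non-blood truth claimed "yes" (false positive), or any
#' positively wrong level.
#'
#' @param truth Truth class label (see \code{\link{sample_spec}}).
#' @param claim A \code{pmf_claim}.
#' @return An object of class \code{scored_sample}: list with
#'   \code{sample_id}, \code{truth}, \code{claim}, \code{verdict},
#'   \code{false_negative}, \code{false_positive}.
#' @export
score_claim <- function(truth, claim) {
  stopifnot(inherits(claim, "pmf_claim"))
  exp <- truth_expectation(truth)
  got <- list(I = claim$level_I_blood, II = claim$level_II_provenance,
              III = claim$level_III_species,
              IV = claim$level_IV_other_biofluid)
  fn <- is_blood_truth(truth) && got$I == "no"
  fp <- !is_blood_truth(truth) && got$I == "yes"

  verdict <- if (identical(exp, got)) {
    "full_correct"
  } else if (fn || fp) {
    "incorrect"
  } else if (is_blood_truth(truth)) {
    # blood detected (or inconclusive): correct-so-far levels decide
    if (got$I == "inconclusive") {
      "partial"
    } else if (got$II == exp$II &&
               got$III %in% c(exp$III, "inconclusive")) {
      "partial"  # e.g. animal blood, species inconclusive
    } else if (got$II == "inconclusive") {
      "partial"
    } else {
      "incorrect"  # positively wrong provenance/species
    }
  } else if (truth == "semen") {
    # not claimed blood, but the semen call is missing or some level is
    # inconclusive: correct at level I only
    "partial"
  } else {
    "incorrect"
  }
  structure(list(sample_id = claim$sample_id, truth = truth, claim = claim,
                 verdict = verdict, false_negative = fn,
                 false_positive = fp),
            class = "scored_sample")
}

category_of <- function(truth) {
  if (truth == "human_blood") return("human")
  if (is_blood_truth(truth)) return("animal")
  if (truth == "semen") return("semen")
  if (truth %in% c("saliva", "sweat")) return("other_biofluid")
  "non_biofluid"
}

#' Summarize a scored cohort
#'
#' Counts and rates over an optional category filter. Percentages are
#' reported to one decimal (conventional rounding) alongside the raw counts,
#' so the rounding convention of any printed figure can be recovered.
#'
#' @param scored List of \code{scored_sample} objects.
#' @param category One of "all", "human", "animal", "semen",
#'   "other_biofluid", "non_biofluid", "blood" (human + animal).
#' @return An object of class \code{cohort_summary}: list with \code{n},
#'   counts (\code{full_correct}, \code{partial}, \code{incorrect},
#'   \code{false_negatives}, \code{false_positives}) and rates
#'   (\code{full_correct_rate}, \code{fn_rate}, \code{fp_rate}, percent).
#' @export
summarize_cohort <- function(scored, category = "all") {
  stopifnot(length(scored) > 0)
  cats <- vapply(scored, function(s) category_of(s$truth), "")
  keep <- switch(category,
    all = rep(TRUE, length(scored)),
    blood = cats %in% c("human", "animal"),
    cats == category
  )
  if (!any(keep))
    stop("category filter '", category, "' selects no samples")
  sub <- scored[keep]
  v <- vapply(sub, `[[`, "", "verdict")
  fn <- vapply(sub, `[[`, logical(1), "false_negative")
  fp <- vapply(sub, `[[`, logical(1), "false_positive")
  n <- length(sub)
  pct <- function(k) round(100 * k / n, 1)
  structure(list(
    category = category, n = n,
    full_correct = sum(v == "full_correct"),
    partial = sum(v == "partial"),
    incorrect = sum(v == "incorrect"),
    false_negatives = sum(fn), false_positives = sum(fp),
    full_correct_rate = pct(sum(v == "full_correct")),
    partial_rate = pct(sum(v == "partial")),
    incorrect_rate = pct(sum(v == "incorrect")),
    fn_rate = pct(sum(fn)), fp_rate = pct(sum(fp))
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "<cohort_summary '%s'> n=%d: %d full (%.1f%%), %d partial, %d incorrect; FN %d (%.1f%%), FP %d (%.1f%%)\n",
    x$category, x$n, x$full_correct, x$full_correct_rate, x$partial,
    x$incorrect, x$false_negatives, x$fn_rate, x$false_positives,
    x$fp_rate))
  invisible(x)
}

#' Classify and score a whole simulated cohort
#'
#' Convenience wrapper: simulate the fixture's peak lists, classify each with
#' the configured strategy, and score against the fixture truths.
#'
#' @param fixture A \code{cohort_fixture}.
#' @param cfg A \code{sim_config}.
#' @param panel A \code{marker_panel}.
#' @param strategy A \code{strategy_config} ("refined" or "initial").
#' @param table Amino-acid table.
#' @return List of \code{scored_sample}, one per fixture sample, named by
#'   sample id.
#' @export
score_cohort <- function(fixture, cfg = sim_config(),
                         panel = marker_panel(),
                         strategy = strategy_config(),
                         table = amino_acid_table()) {
  sims <- cohort_peaklists(fixture, cfg, panel, preprocess = TRUE, table)
  out <- lapply(sims, function(s) {
    claim <- classify(s$peaks, panel, strategy, table)
    score_claim(s$truth, claim)
  })
  names(out) <- names(sims)
  out
}

#' Write a rendered cohort report
#'
#' TSV table mirroring the blind-sample report columns (sample, enhancement,
#' claimed levels, truth, verdict) plus a caption line with the headline
#' rate.
#'
#' @param scored List of \code{scored_sample}.
#' @param path Output path.
#' @return The report data.frame, invisibly.
#' @export
report_cohort <- function(scored, path) {
  if (!nzchar(path)) stop("report path must be non-empty")
  df <- do.call(rbind, lapply(scored, function(s) {
    data.frame(sample_id = s$sample_id,
               level_I = s$claim$level_I_blood,
               level_II = s$claim$level_II_provenance,
               level_III = s$claim$level_III_species,
               level_IV = s$claim$level_IV_other_biofluid,
               truth = s$truth, verdict = s$verdict,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  s <- summarize_cohort(scored, "all")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d/%d fully correct (%.1f%%)", s$full_correct, s$n,
                     s$full_correct_rate), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
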