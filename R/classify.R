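#' Strategy configuration for the decision tree
#'
#' Defaults reproduce the refined interpretation settings: S/N threshold 10,
#' 30 ppm candidate matching, 15 ppm confirmation. Setting
#' \code{bovine_from_myoglobin_alone = TRUE} lets the bovine myoglobin marker
#' (nominal 1593) claim bovine blood without the mammalian GAPDH marker; by
#' default that pattern yields animal blood with species inconclusive.
#'
#' @param candidate_ppm Candidate match window (ppm).
#' @param confirm_ppm Confirmation window (ppm).
#' @param snr_min S/N threshold the peak list must have been filtered at.
#' @param version "refined" or "initial" (human-haemoglobin-only).
#' @param bovine_from_myoglobin_alone See description.
#' @return An object of class \code{strategy_config}.
#' @export
strategy_config <- function(candidate_ppm = 30, confirm_ppm = 15,
                            snr_min = 10,
                            version = c("refined", "initial"),
                            bovine_from_myoglobin_alone = FALSE) {
  version <- match.arg(version)
  stopifnot(confirm_ppm > 0, confirm_ppm <= candidate_ppm, snr_min > 0)
  structure(list(candidate_ppm = candidate_ppm, confirm_ppm = confirm_ppm,
                 snr_min = snr_min, version = version,
                 bovine_from_myoglobin_alone =
                   isTRUE(bovine_from_myoglobin_alone)),
            class = "strategy_config")
}

new_claim <- function(level_I, level_II, level_III, level_IV, branch,
                      notes = character(0), evidence = NULL,
                      sample_id = "") {
  stopifnot(level_I %in% c("yes", "no", "inconclusive"),
            level_II %in% c("human", "animal", "n/a", "inconclusive"),
            level_III %in% c("chicken", "bovine", "porcine", "inconclusive",
                             "n/a"),
            level_IV %in% c("semen", "none-detected"))
  if (level_II != "n/a" && level_I != "yes")
    stop("level II can only be claimed when blood is present")
  if (level_III != "n/a" && level_II != "animal")
    stop("level III can only be claimed for animal blood")
  structure(list(sample_id = sample_id, level_I_blood = level_I,
                 level_II_provenance = level_II, level_III_species = level_III,
                 level_IV_other_biofluid = level_IV, branch = branch,
                 notes = notes, evidence = evidence),
            class = "pmf_claim")
}

#' @export
print.pmf_claim <- function(x, ...) {
  cat(explain(x), sep = "\n")
  invisible(x)
}

check_preprocessed <- function(pl) {
  h <- attr(pl, "history")
  need <- c("filter_snr", "restrict_range")
  got <- vapply(need, function(s) any(startsWith(h, s)), logical(1))
  if (!all(got))
    stop("peak list is not preprocessed: missing history entries ",
         paste(need[!got], collapse = ", "),
         " (see preprocess_peaklist())")
  invisible(pl)
}

confirmed <- function(res, id) {
  i <- match(id, res$marker_id)
  !is.na(i) && res$stage[i] == "confirmed"
}

nominal_hit <- function(res, id) {
  i <- match(id, res$marker_id)
  !is.na(i) && isTRUE(res$nominal_hit[i])
}

#' Classify a peak list with the refined decision tree
#'
#' Maps confirmed marker matches to an identity claim across the
#' identification levels: (I) blood present, (II) human vs animal, (III)
#' animal species, (IV) other biofluid (semen). Exactly one branch fires, in
#' order: human blood (both shared HB peptides confirmed; semen co-presence
#' appended as a note, with the bovine-sequence-overlap caveat); chicken
#' (chicken GAPDH, nominal 1750); bovine (mammalian GAPDH, nominal 1764, plus
#' myoglobin nominal 1593 and/or putative 1670); porcine (mammalian GAPDH
#' without myoglobin; porcine-myoglobin nominal 649 raises confidence);
#' myoglobin without GAPDH (animal blood, species inconclusive, or bovine if
#' so configured); semen (SEM-1, or both semenogelin supports 1445 and 1555);
#' a single HB peptide alone (level I inconclusive, MS/MS recommended);
#' otherwise no blood.
#'
#' @param pl A preprocessed \code{peak_list} (the processing history must
#'   show the S/N filter and range restriction).
#' @param panel A \code{marker_panel}.
#' @param cfg A \code{strategy_config}.
#' @param table Amino-acid table.
#' @return An object of class \code{pmf_claim}.
#' @export
classify <- function(pl, panel = marker_panel(), cfg = strategy_config(),
                     table = amino_acid_table()) {
  if (cfg$version == "initial")
    return(classify_initial(pl, panel, cfg, table))
  check_preprocessed(pl)
  res <- match_panel(pl, panel, cfg$candidate_ppm, cfg$confirm_ppm, table)
  sid <- attr(pl, "sample_id")

  hbb <- confirmed(res, "hbb_shared")
  hba <- confirmed(res, "hba_shared")
  chick <- confirmed(res, "gapdh_chicken")
  mammal <- confirmed(res, "gapdh_mammal")
  myo <- confirmed(res, "myo_1593") || confirmed(res, "myo_1670")
  sem <- confirmed(res, "sem1") ||
    (confirmed(res, "sem_1445") && confirmed(res, "sem_1555"))

  notes <- character(0)
  sup_ids <- res$marker_id[res$role == "supporting" &
                             res$stage == "confirmed"]
  if (length(sup_ids))
    notes <- c(notes, paste0("supporting markers confirmed: ",
                             paste(sup_ids, collapse = ", ")))
  nom_ids <- res$marker_id[res$role == "nominal-support" & res$nominal_hit]
  if (length(nom_ids))
    notes <- c(notes, paste0("nominal-support signals present: ",
                             paste(nom_ids, collapse = ", ")))

  if (hbb && hba) {
    notes <- c(notes,
               "caveat: both shared HB peptides also occur in bovine HB")
    if (sem)
      notes <- c(notes, paste("possible blood/semen co-presence;",
                              "confirmatory MS/MS analysis recommended"))
    return(new_claim("yes", "human", "n/a", "none-detected", "human",
                     notes, res, sid))
  }
  if (chick)
    return(new_claim("yes", "animal", "chicken", "none-detected", "chicken",
                     notes, res, sid))
  if (mammal && myo)
    return(new_claim("yes", "animal", "bovine", "none-detected", "bovine",
                     notes, res, sid))
  if (mammal) {
    if (nominal_hit(res, "myo_porcine_649"))
      notes <- c(notes,
                 "confidence raised: porcine myoglobin nominal 649 present")
    return(new_claim("yes", "animal", "porcine", "none-detected", "porcine",
                     notes, res, sid))
  }
  if (myo) {
    if (cfg$bovine_from_myoglobin_alone)
      return(new_claim("yes", "animal", "bovine", "none-detected",
                       "myoglobin-alone", notes, res, sid))
    return(new_claim("yes", "animal", "inconclusive", "none-detected",
                     "myoglobin-alone", notes, res, sid))
  }
  if (sem)
    return(new_claim("no", "n/a", "n/a", "semen", "semen", notes, res, sid))
  if (xor(hbb, hba)) {
    notes <- c(notes, paste("only one shared HB peptide confirmed;",
                            "MS/MS confirmation recommended"))
    return(new_claim("inconclusive", "n/a", "n/a", "none-detected",
                     "single-HB", notes, res, sid))
  }
  new_claim("no", "n/a", "n/a", "none-detected", "no-blood", notes, res, sid)
}

#' Classify with the initial (human-haemoglobin-only) strategy
#'
#' The pre-refinement strategy: only the human-blood branch, the
#' single-HB-inconclusive branch and the no-blood branch are active; animal
#' and semen markers are ignored (which is what historically produced the
#' animal-blood false negatives). Human proteotypic supports are recorded as
#' confidence notes.
#'
#' @inheritParams classify
#' @return A \code{pmf_claim}.
#' @export
classify_initial <- function(pl, panel = marker_panel(),
                             cfg = strategy_config(version = "initial"),
                             table = amino_acid_table()) {
  check_preprocessed(pl)
  res <- match_panel(pl, panel, cfg$candidate_ppm, cfg$confirm_ppm, table)
  sid <- attr(pl, "sample_id")
  hbb <- confirmed(res, "hbb_shared")
  hba <- confirmed(res, "hba_shared")
  notes <- character(0)
  hu_sup <- intersect(c("hu_hbb_932", "hu_epb42_1087", "hu_hpt_1378"),
                      res$marker_id[res$stage == "confirmed"])
  if (length(hu_sup))
    notes <- c(notes, paste0("human proteotypic supports confirmed: ",
                             paste(hu_sup, collapse = ", ")))
  if (hbb && hba)
    return(new_claim("yes", "human", "n/a", "none-detected", "human",
                     notes, res, sid))
  if (xor(hbb, hba)) {
    notes <- c(notes, paste("only one shared HB peptide confirmed;",
                            "MS/MS confirmation recommended"))
    return(new_claim("inconclusive", "n/a", "n/a", "none-detected",
                     "single-HB", notes, res, sid))
  }
  new_claim("no", "n/a", "n/a", "none-detected", "no-blood", notes, res, sid)
}

#' Human-readable report for a claim
#'
#' Lists the final claim per identification level, the branch that fired,
#' every marker hit with its ppm error, and the confidence notes.
#'
#' @param claim A \code{pmf_claim}.
#' @return Character vector of report lines.
#' @export
explain <- function(claim) {
  stopifnot(inherits(claim, "pmf_claim"))
  lines <- c(
    sprintf("Sample: %s", claim$sample_id),
    sprintf("Level I   (blood?):          %s", claim$level_I_blood),
    sprintf("Level II  (human/animal):    %s", claim$level_II_provenance),
    sprintf("Level III (animal species):  %s", claim$level_III_species),
    sprintf("Level IV  (other biofluid):  %s", claim$level_IV_other_biofluid),
    sprintf("Branch fired: %s", claim$branch)
  )
  ev <- claim$evidence
  if (!is.null(ev) && nrow(ev)) {
    hit <- ev[ev$stage != "unmatched" | ev$nominal_hit, , drop = FALSE]
    if (nrow(hit)) {
      lines <- c(lines, "Markers detected:")
      for (i in seq_len(nrow(hit))) {
        if (hit$stage[i] != "unmatched") {
          lines <- c(lines, sprintf(
            "  %-16s %s at m/z %.3f (%+.1f ppm)", hit$marker_id[i],
            hit$stage[i], hit$matched_mz[i], hit$ppm[i]))
        } else {
          lines <- c(lines, sprintf(
            "  %-16s nominal window hit (+/- 0.5 Th of %s)",
            hit$marker_id[i], "its nominal m/z"))
        }
      }
    } else {
      lines <- c(lines, "No blood or semen markers detected.")
    }
  }
  if (claim$level_I_blood == "no" &&
      claim$level_IV_other_biofluid == "none-detected")
    lines <- c(lines, "Conclusion: no blood detected.")
  if (length(claim$notes))
    lines <- c(lines, "Notes:", paste0("  - ", claim$notes))
  lines
}
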