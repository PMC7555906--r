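#' Construct a diagnostic marker
#'
#' A marker is a diagnostic peptide for a biofluid/species combination. Its
#' center can be sequence-backed (MH+ computed from the residue string),
#' a literal m/z (used when the peptide identity is putative), or
#' nominal-only (integer label with no exact center: such markers are
#' inactive for claim-driving matching and can only raise confidence, matched
#' within +/- 0.5 Th of the nominal value).
#'
#' @param id Unique marker id.
#' @param protein Protein name (e.g. "HBB", "GAPDH").
#' @param accession UniProt accession ("" if not pinned).
#' @param biofluid "blood" or "semen".
#' @param species Character vector of species sharing the peptide.
#' @param role "primary" (drives claims), "supporting" (confidence), or
#'   "nominal-support" (confidence only, nominal window matching).
#' @param sequence Peptide sequence (sequence-backed center), or NULL.
#' @param literal_mz Literal center m/z (Th), or NULL.
#' @param nominal Integer nominal m/z label; derived from the center when
#'   resolvable.
#' @param table Amino-acid table.
#' @return An object of class \code{pmf_marker}.
#' @export
marker <- function(id, protein, accession = "", biofluid = c("blood", "semen"),
                   species, role = c("primary", "supporting",
                                     "nominal-support"),
                   sequence = NULL, literal_mz = NULL, nominal = NULL,
                   table = amino_acid_table()) {
  biofluid <- match.arg(biofluid)
  role <- match.arg(role)
  if (is.null(sequence) && is.null(literal_mz) && is.null(nominal))
    stop("marker '", id, "' needs a sequence, a literal m/z or a nominal m/z")
  m <- structure(list(id = id, protein = protein, accession = accession,
                      biofluid = biofluid, species = species, role = role,
                      sequence = sequence, literal_mz = literal_mz,
                      nominal = nominal),
                 class = "pmf_marker")
  center <- resolve_center(m, table)
  if (is.null(nominal)) {
    m$nominal <- if (is.na(center)) NA_integer_ else nominal_mz(center)
  } else {
    m$nominal <- as.integer(nominal)
  }
  m
}

#' Resolve a marker's exact center m/z
#'
#' Sequence-backed markers return the computed MH+ (sequence-derived centers
#' take precedence over printed observed values: observed values carry
#' instrument error that the 15 ppm confirmation window absorbs); literal
#' markers return the stored value; nominal-only markers are unresolvable and
#' return NA (inactive).
#'
#' @param m A \code{pmf_marker}.
#' @param table Amino-acid table.
#' @return Center m/z in Th, or NA for an inactive (nominal-only) marker.
#' @export
resolve_center <- function(m, table = amino_acid_table()) {
  if (!is.null(m$sequence)) return(peptide_mz(m$sequence, table = table))
  if (!is.null(m$literal_mz)) return(as.numeric(m$literal_mz))
  NA_real_
}

#' Is a marker active (claim-capable)?
#'
#' Active markers have a resolvable exact center; nominal-only markers are
#' inactive and only contribute confidence notes.
#'
#' @param m A \code{pmf_marker}.
#' @param table Amino-acid table.
#' @return Logical.
#' @export
is_active_marker <- function(m, table = amino_acid_table()) {
  !is.na(resolve_center(m, table))
}

#' @export
print.pmf_marker <- function(x, ...) {
  ctr <- resolve_center(x)
  cat(sprintf("<marker %s> %s (%s) %s [%s] center %s nominal %s\n",
              x$id, x$protein, paste(x$species, collapse = "/"), x$biofluid,
              x$role,
              if (is.na(ctr)) "unresolved" else sprintf("%.3f", ctr),
              x$nominal))
  invisible(x)
}

#' The default diagnostic marker panels
#'
#' \code{version = "refined"} builds the full panel behind the refined
#' decision tree: shared haemoglobin peptides (beta-chain LLVVYPWTQR, shared
#' human/porcine/bovine; alpha-chain VGGHAAEYGAEALER, shared human/bovine),
#' human-proteotypic literal supports (932.520 beta-HB; 1087.553 EPB42;
#' 1378.694 haptoglobin), chicken GAPDH LVSWYDNEFGYSNR (nominal 1750) with
#' nominal supports 795/805/1033/1359/1646, mammalian GAPDH LISWYDNEFGYSNR
#' (nominal 1764, bovine/porcine), bovine myoglobin VEADVAGHGQEVLIR (nominal
#' 1593) and putative literal 1669.837, porcine myoglobin nominal 649
#' (inactive unless a center is configured), and semenogelin markers: SEM-1
#' GLRPSEFSQFPHGQK (nominal 1715) with literal supports 1444.764 (SEM-1/2)
#' and 1554.779 (SEM-2) plus optional literals 1501.744 / 1801.918 /
#' 1883.936.
#'
#' \code{version = "initial"} is the historical human-haemoglobin-only panel
#' (the two shared HB peptides plus the human literal supports).
#'
#' @param version "refined" (default) or "initial".
#' @param table Amino-acid table.
#' @return An object of class \code{marker_panel} (list with \code{markers},
#'   \code{version}).
#' @export
marker_panel <- function(version = c("refined", "initial"),
                         table = amino_acid_table()) {
  version <- match.arg(version)
  hb <- list(
    marker("hbb_shared", "HBB", "", "blood",
           c("human", "porcine", "bovine"), "primary",
           sequence = "LLVVYPWTQR", table = table),
    marker("hba_shared", "HBA", "", "blood", c("human", "bovine"), "primary",
           sequence = "VGGHAAEYGAEALER", table = table),
    marker("hu_hbb_932", "HBB", "", "blood", "human", "supporting",
           literal_mz = 932.520, table = table),
    marker("hu_epb42_1087", "EPB42", "P16452", "blood", "human", "supporting",
           literal_mz = 1087.553, table = table),
    marker("hu_hpt_1378", "Hpt", "P00738", "blood", "human", "supporting",
           literal_mz = 1378.694, table = table)
  )
  if (version == "initial")
    return(structure(list(markers = hb, version = version),
                     class = "marker_panel"))
  animal <- list(
    marker("gapdh_chicken", "GAPDH", "P00356", "blood", "chicken", "primary",
           sequence = "LVSWYDNEFGYSNR", table = table),
    marker("gapdh_ck_795", "GAPDH", "P00356", "blood", "chicken",
           "nominal-support", nominal = 795, table = table),
    marker("gapdh_ck_805", "GAPDH", "P00356", "blood", "chicken",
           "nominal-support", nominal = 805, table = table),
    marker("gapdh_ck_1033", "GAPDH", "P00356", "blood", "chicken",
           "nominal-support", nominal = 1033, table = table),
    marker("gapdh_ck_1359", "GAPDH", "P00356", "blood", "chicken",
           "nominal-support", nominal = 1359, table = table),
    marker("gapdh_ck_1646", "GAPDH", "P00356", "blood", "chicken",
           "nominal-support", nominal = 1646, table = table),
    marker("gapdh_mammal", "GAPDH", "", "blood", c("bovine", "porcine"),
           "primary", sequence = "LISWYDNEFGYSNR", table = table),
    marker("myo_1593", "myoglobin", "P02192", "blood", "bovine", "primary",
           sequence = "VEADVAGHGQEVLIR", table = table),
    marker("myo_1670", "myoglobin", "P02192", "blood", "bovine", "supporting",
           literal_mz = 1669.837, table = table),
    marker("myo_porcine_649", "myoglobin", "P02189", "blood", "porcine",
           "nominal-support", nominal = 649, table = table)
  )
  semen <- list(
    marker("sem1", "SEM-1", "P04279", "semen", "human", "primary",
           sequence = "GLRPSEFSQFPHGQK", table = table),
    marker("sem_1445", "SEM-1/2", "", "semen", "human", "supporting",
           literal_mz = 1444.764, table = table),
    marker("sem_1555", "SEM-2", "", "semen", "human", "supporting",
           literal_mz = 1554.779, table = table),
    marker("sem_1501", "SEM-1", "", "semen", "human", "supporting",
           literal_mz = 1501.744, table = table),
    marker("sem_1801", "SEM-1", "", "semen", "human", "supporting",
           literal_mz = 1801.918, table = table),
    marker("sem_1883", "SEM-2", "", "semen", "human", "supporting",
           literal_mz = 1883.936, table = table)
  )
  markers <- c(hb, animal, semen)
  ids <- vapply(markers, `[[`, "", "id")
  stopifnot(!anyDuplicated(ids))
  structure(list(markers = markers, version = version),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("<marker_panel '%s'> %d markers\n", x$version,
              length(x$markers)))
  for (m in x$markers) print(m)
  invisible(x)
}

panel_marker <- function(panel, id) {
  for (m in panel$markers) if (m$id == id) return(m)
  NULL
}

#' Match one marker against a peak list
#'
#' For an active marker: the peak with the smallest absolute ppm error within
#' \code{candidate_ppm} is selected (ties broken toward higher intensity,
#' then lower m/z); the match is \code{"confirmed"} when |ppm| <=
#' \code{confirm_ppm}, otherwise \code{"candidate"}. For a nominal-only
#' marker the stage is always \code{"unmatched"} but \code{nominal_hit}
#' records whether any peak lies within +/- 0.5 Th of the nominal value
#' (confidence only).
#'
#' @param pl A preprocessed \code{peak_list}.
#' @param m A \code{pmf_marker}.
#' @param candidate_ppm Candidate window (default 30 ppm).
#' @param confirm_ppm Confirmation window (default 15 ppm, must be <=
#'   candidate).
#' @param table Amino-acid table.
#' @return One-row data.frame: \code{marker_id}, \code{role},
#'   \code{biofluid}, \code{active}, \code{center}, \code{matched_mz},
#'   \code{intensity}, \code{ppm}, \code{stage}, \code{nominal_hit}.
#' @export
match_marker <- function(pl, m, candidate_ppm = 30, confirm_ppm = 15,
                         table = amino_acid_table()) {
  stopifnot(confirm_ppm > 0, confirm_ppm <= candidate_ppm)
  center <- resolve_center(m, table)
  nominal_hit <- !is.na(m$nominal) && nrow(pl) > 0 &&
    any(abs(pl$mz - m$nominal) <= 0.5)
  row <- data.frame(marker_id = m$id, role = m$role, biofluid = m$biofluid,
                    active = !is.na(center), center = center,
                    matched_mz = NA_real_, intensity = NA_real_,
                    ppm = NA_real_, stage = "unmatched",
                    nominal_hit = nominal_hit, stringsAsFactors = FALSE)
  if (is.na(center) || !nrow(pl)) return(row)
  ppm <- ppm_error(pl$mz, center)
  within <- which(abs(ppm) <= candidate_ppm)
  if (!length(within)) return(row)
  o <- within[order(abs(ppm[within]), -pl$intensity[within], pl$mz[within])]
  best <- o[1L]
  row$matched_mz <- pl$mz[best]
  row$intensity <- pl$intensity[best]
  row$ppm <- ppm[best]
  row$stage <- if (abs(ppm[best]) <= confirm_ppm) "confirmed" else "candidate"
  row
}

#' Match a whole marker panel against a peak list
#'
#' One row per marker (inactive markers included, flagged); deterministic for
#' fixed input.
#'
#' @inheritParams match_marker
#' @param panel A \code{marker_panel}.
#' @return data.frame with one \code{match_marker} row per marker.
#' @export
match_panel <- function(pl, panel = marker_panel(), candidate_ppm = 30,
                        confirm_ppm = 15, table = amino_acid_table()) {
  stopifnot(inherits(panel, "marker_panel"))
  do.call(rbind, lapply(panel$markers, match_marker, pl = pl,
                        candidate_ppm = candidate_ppm,
                        confirm_ppm = confirm_ppm, table = table))
}

#' Annotate every peak against a theoretical digest table
#'
#' Each peak is annotated with every table entry within the candidate
#' tolerance (binary search over the m/z-sorted table), tagged
#' confirmed/candidate and proteotypic/shared; peaks matching more than one
#' entry within the confirmation window are flagged ambiguous.
#'
#' @param pl A \code{peak_list}.
#' @param tt A \code{theoretical_table} (sorted by m/z).
#' @param candidate_ppm,confirm_ppm Two-stage tolerances (30 / 15 ppm).
#' @return data.frame with columns \code{peak_mz}, \code{peak_intensity},
#'   \code{accession}, \code{species}, \code{sequence},
#'   \code{oxidized_positions}, \code{missed_cleavages}, \code{theoretical_mz},
#'   \code{ppm}, \code{stage}, \code{specificity}, \code{ambiguous}.
#' @export
annotate_against_table <- function(pl, tt, candidate_ppm = 30,
                                   confirm_ppm = 15) {
  stopifnot(confirm_ppm > 0, confirm_ppm <= candidate_ppm)
  empty <- data.frame(peak_mz = numeric(0), peak_intensity = numeric(0),
                      accession = character(0), species = character(0),
                      sequence = character(0),
                      oxidized_positions = character(0),
                      missed_cleavages = integer(0),
                      theoretical_mz = numeric(0), ppm = numeric(0),
                      stage = character(0), specificity = character(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE)
  if (!nrow(pl) || !nrow(tt)) return(empty)
  tmz <- tt$mz
  if (is.unsorted(tmz)) stop("theoretical table must be sorted by mz")
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(pl))) {
    p <- pl$mz[i]
    # prefilter window in Th; slightly widened so the exact ppm test below
    # (relative to the theoretical mass) cannot lose edge entries
    tol <- p * candidate_ppm * 1.01 / 1e6
    lo <- findInterval(p - tol, tmz) + 1L
    hi <- findInterval(p + tol, tmz)
    if (hi < lo) next
    idx <- lo:hi
    ppm <- ppm_error(p, tmz[idx])
    idx <- idx[abs(ppm) <= candidate_ppm]
    ppm <- ppm[abs(ppm) <= candidate_ppm]
    if (!length(idx)) next
    stage <- ifelse(abs(ppm) <= confirm_ppm, "confirmed", "candidate")
    amb <- sum(stage == "confirmed") > 1L
    k <- k + 1L
    rows[[k]] <- data.frame(
      peak_mz = p, peak_intensity = pl$intensity[i],
      accession = tt$accession[idx], species = tt$species[idx],
      sequence = tt$sequence[idx],
      oxidized_positions = tt$oxidized_positions[idx],
      missed_cleavages = tt$missed_cleavages[idx],
      theoretical_mz = tmz[idx], ppm = ppm, stage = stage,
      specificity = tt$specificity[idx], ambiguous = amb,
      stringsAsFactors = FALSE
    )
  }
  if (!k) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
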