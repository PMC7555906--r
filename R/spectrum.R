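#' Construct a centroided peak list
#'
#' A peak list is one sample's centroided peaks (m/z, intensity, optional
#' S/N), kept strictly sorted in m/z with duplicate m/z rows merged keeping
#' the maximum intensity. Every filter appends to the processing history.
#'
#' @param mz Peak positions (Th, > 0).
#' @param intensity Intensities (arbitrary units, >= 0).
#' @param snr Signal-to-noise ratios (NA = unknown).
#' @param sample_id Sample identifier.
#' @param metadata Named list (enhancement tag, source file, ...).
#' @param history Character vector of processing steps already applied.
#' @return An object of class \code{peak_list} (a data.frame with columns
#'   \code{mz}, \code{intensity}, \code{snr} and attributes \code{sample_id},
#'   \code{metadata}, \code{history}).
#' @export
peak_list <- function(mz = numeric(0), intensity = numeric(0),
                      snr = rep(NA_real_, length(mz)),
                      sample_id = "", metadata = list(),
                      history = character(0)) {
  stopifnot(length(mz) == length(intensity), length(mz) == length(snr))
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("peak m/z must be positive")
  if (any(intensity < 0, na.rm = TRUE)) stop("peak intensity must be >= 0")
  df <- data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity),
                   snr = as.numeric(snr))
  df <- df[order(df$mz, -df$intensity), , drop = FALSE]
  df <- df[!duplicated(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, sample_id = sample_id, metadata = metadata,
            history = history, class = c("peak_list", "data.frame"))
}

pl_rebuild <- function(pl, keep, step) {
  out <- as.data.frame(pl)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            sample_id = attr(pl, "sample_id"),
            metadata = attr(pl, "metadata"),
            history = c(attr(pl, "history"), step),
            class = c("peak_list", "data.frame"))
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> sample '%s': %d peaks", attr(x, "sample_id"),
              nrow(x)))
  if (nrow(x)) cat(sprintf(", m/z %.3f-%.3f", min(x$mz), max(x$mz)))
  cat("\n")
  h <- attr(x, "history")
  if (length(h)) cat("  history:", paste(h, collapse = " -> "), "\n")
  invisible(x)
}

#' Read a centroided peak list from a plain-text export
#'
#' Whitespace- or tab-delimited columns m/z, intensity and (optionally) S/N,
#' as produced by common spectrum viewers when exporting mass lists to .txt.
#' Lines starting with \code{#} are ignored. Duplicate m/z rows are merged
#' keeping the maximum intensity.
#'
#' @param path File path.
#' @param sample_id Sample identifier (default: file base name).
#' @return A \code{peak_list}.
#' @export
read_peaklist <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such peak list: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (!length(body)) stop("no parseable rows in ", path)
  fields <- strsplit(trimws(body), "[\t ]+")
  ncol <- lengths(fields)
  if (any(ncol < 2L))
    stop(sprintf("row at line %d has fewer than 2 columns",
                 lineno[which(ncol < 2L)[1L]]))
  mz <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  it <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  sn <- suppressWarnings(as.numeric(vapply(fields, function(f)
    if (length(f) >= 3L) f[3L] else NA_character_, "")))
  bad <- which(is.na(mz) | is.na(it))
  if (length(bad))
    stop(sprintf("unparseable numeric value at line %d", lineno[bad[1L]]))
  neg <- which(it < 0)
  if (length(neg))
    stop(sprintf("negative intensity at line %d", lineno[neg[1L]]))
  if (is.null(sample_id)) sample_id <- basename(path)
  peak_list(mz, it, sn, sample_id = sample_id,
            metadata = list(source_file = path),
            history = "read_peaklist")
}

#' Write a peak list as plain text
#'
#' Three tab-separated columns (m/z at 6 decimals, intensity, S/N), preceded
#' by a \code{#} header naming the sample and processing history, so a
#' write/read round trip is stable at the reported precision.
#'
#' @param pl A \code{peak_list}.
#' @param path Output path.
#' @export
write_peaklist <- function(pl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample: %s", attr(pl, "sample_id")), con)
  h <- attr(pl, "history")
  if (length(h)) writeLines(sprintf("# history: %s",
                                    paste(h, collapse = " -> ")), con)
  writeLines("# mz\tintensity\tsnr", con)
  if (nrow(pl)) {
    writeLines(sprintf("%.6f\t%.6g\t%s", pl$mz, pl$intensity,
                       ifelse(is.na(pl$snr), "NA",
                              sprintf("%.6g", pl$snr))), con)
  }
  invisible(path)
}

#' Keep peaks at or above a signal-to-noise threshold
#'
#' The boundary is inclusive ("S/N of 10 or above"). Peaks with unknown S/N
#' are retained and the list is flagged (\code{unknown_snr_retained} in the
#' metadata) rather than silently dropped.
#'
#' @param pl A \code{peak_list}.
#' @param threshold Positive S/N threshold (default 10).
#' @return Filtered \code{peak_list}.
#' @export
filter_snr <- function(pl, threshold = 10) {
  stopifnot(threshold > 0)
  unknown <- is.na(pl$snr)
  keep <- unknown | pl$snr >= threshold
  out <- pl_rebuild(pl, keep, sprintf("filter_snr(%g)", threshold))
  if (any(unknown[keep])) {
    md <- attr(out, "metadata")
    md$unknown_snr_retained <- sum(unknown[keep])
    attr(out, "metadata") <- md
  }
  out
}

#' Exclusion list of known contaminant ions
#'
#' Matrix (cluster/adduct) and trypsin-autolysis ions to be removed from peak
#' labelling. Entries are (m/z, label) pairs matched within a ppm tolerance.
#'
#' @param mz Entry m/z values (Th).
#' @param label Entry labels.
#' @param tolerance_ppm Matching tolerance (ppm, > 0).
#' @param name List name.
#' @return An object of class \code{exclusion_list}.
#' @export
exclusion_list <- function(mz, label = sprintf("excl_%d", seq_along(mz)),
                           tolerance_ppm = 15, name = "exclusion") {
  stopifnot(length(mz) == length(label), tolerance_ppm > 0)
  if (any(mz <= 0)) stop("exclusion m/z must be positive")
  structure(list(name = name,
                 entries = data.frame(mz = as.numeric(mz),
                                      label = as.character(label),
                                      stringsAsFactors = FALSE),
                 tolerance_ppm = tolerance_ppm),
            class = "exclusion_list")
}

#' Default matrix / autolysis exclusion list
#'
#' CHCA matrix cluster ions ([nM+H]+ series inside 600-2000 Th) plus two
#' porcine trypsin autolysis ions. These are documented plumbing defaults for
#' routine CHCA / trypsin work, not values taken from any particular study,
#' and are fully overridable.
#'
#' @param tolerance_ppm Matching tolerance (default 15 ppm).
#' @return An \code{exclusion_list}.
#' @export
default_exclusion_list <- function(tolerance_ppm = 15) {
  chca <- 189.042593                        # CHCA monoisotopic mass
  n <- 4:10
  cluster <- n * chca + 1.007276            # [nM+H]+ within 600-2000 Th
  exclusion_list(
    mz = c(cluster, 842.5100, 1045.5642),
    label = c(sprintf("CHCA_[%dM+H]+", n),
              "trypsin_autolysis_842", "trypsin_autolysis_1045"),
    tolerance_ppm = tolerance_ppm,
    name = "chca_trypsin_defaults"
  )
}

#' Remove peaks matching an exclusion list
#'
#' Peaks within \code{tolerance_ppm} of any exclusion entry are removed;
#' removals are logged (with the matching entry label) in the metadata under
#' \code{excluded_peaks}.
#'
#' @param pl A \code{peak_list}.
#' @param ex An \code{exclusion_list}.
#' @return Filtered \code{peak_list}.
#' @export
apply_exclusion <- function(pl, ex = default_exclusion_list()) {
  stopifnot(inherits(ex, "exclusion_list"))
  if (!nrow(ex$entries)) stop("exclusion list has no entries")
  hit_label <- rep(NA_character_, nrow(pl))
  if (nrow(pl)) {
    for (i in seq_len(nrow(ex$entries))) {
      d <- abs(ppm_error(pl$mz, ex$entries$mz[i]))
      hit <- d <= ex$tolerance_ppm & is.na(hit_label)
      hit_label[hit] <- ex$entries$label[i]
    }
  }
  keep <- is.na(hit_label)
  out <- pl_rebuild(pl, keep, sprintf("apply_exclusion(%s)", ex$name))
  if (any(!keep)) {
    md <- attr(out, "metadata")
    md$excluded_peaks <- data.frame(mz = pl$mz[!keep],
                                    label = hit_label[!keep],
                                    stringsAsFactors = FALSE)
    attr(out, "metadata") <- md
  }
  out
}

#' Restrict a peak list to an m/z window
#'
#' Inclusive bounds; the default acquisition window is 600-2000 Th.
#'
#' @param pl A \code{peak_list}.
#' @param lo,hi Window bounds in Th, \code{lo < hi}.
#' @return Filtered \code{peak_list}.
#' @export
restrict_range <- function(pl, lo = 600, hi = 2000) {
  if (!(lo < hi)) stop("invalid m/z window: lo must be < hi")
  pl_rebuild(pl, pl$mz >= lo & pl$mz <= hi,
             sprintf("restrict_range(%g,%g)", lo, hi))
}

#' Standard preprocessing chain
#'
#' Applies, in order: S/N threshold, exclusion list, acquisition-window
#' restriction. The three filters are idempotent and commute, so the order is
#' a convention, not a requirement.
#'
#' @param pl A \code{peak_list}.
#' @param snr_min S/N threshold (default 10).
#' @param exclusion An \code{exclusion_list} or NULL to skip.
#' @param lo,hi m/z window (default 600-2000 Th).
#' @return Preprocessed \code{peak_list}.
#' @export
preprocess_peaklist <- function(pl, snr_min = 10,
                                exclusion = default_exclusion_list(),
                                lo = 600, hi = 2000) {
  pl <- filter_snr(pl, snr_min)
  if (!is.null(exclusion)) pl <- apply_exclusion(pl, exclusion)
  restrict_range(pl, lo, hi)
}
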