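# Independent oracles and small fixture builders used across the suite.

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

# Brute-force tryptic digest: tests every substring of the sequence against
# the cleavage rule (cut after K/R unless followed by P) directly, without
# using any package code. Returns unique (sequence, missed_cleavages) pairs.
brute_force_digest <- function(seqstr, max_missed) {
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  is_site <- function(i) {
    i >= 1 && i < n && chars[i] %in% c("K", "R") && chars[i + 1L] != "P"
  }
  out <- list(); k <- 0L
  for (s in 1:n) {
    if (!(s == 1L || is_site(s - 1L))) next
    for (e in s:n) {
      if (!(e == n || is_site(e))) next
      internal <- if (e > s) sum(vapply(s:(e - 1L), is_site, logical(1))) else 0L
      if (internal > max_missed) next
      k <- k + 1L
      out[[k]] <- data.frame(sequence = substr(seqstr, s, e),
                             missed_cleavages = internal,
                             stringsAsFactors = FALSE)
    }
  }
  unique(do.call(rbind, out))
}

# All-pairs peak-vs-table annotation oracle (no sorting, no binary search).
brute_force_annotate <- function(pl, tt, candidate_ppm, confirm_ppm) {
  hits <- list(); k <- 0L
  for (i in seq_len(nrow(pl))) {
    for (j in seq_len(nrow(tt))) {
      ppm <- (pl$mz[i] - tt$mz[j]) / tt$mz[j] * 1e6
      if (abs(ppm) <= candidate_ppm) {
        k <- k + 1L
        hits[[k]] <- data.frame(
          peak_mz = pl$mz[i], sequence = tt$sequence[j],
          theoretical_mz = tt$mz[j], ppm = ppm,
          stage = if (abs(ppm) <= confirm_ppm) "confirmed" else "candidate",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!k) return(data.frame(peak_mz = numeric(0), sequence = character(0),
                            theoretical_mz = numeric(0), ppm = numeric(0),
                            stage = character(0)))
  do.call(rbind, hits)
}

# A preprocessed peak list placed exactly at the given m/z values.
exact_peaklist <- function(mz, sample_id = "test", snr = 50) {
  pl <- peak_list(mz, intensity = rep(100, length(mz)),
                  snr = rep(snr, length(mz)), sample_id = sample_id)
  preprocess_peaklist(pl, exclusion = NULL)
}

marker_fasta <- function() {
  system.file("extdata", "synthetic_markers.fasta", package = "bloodPMF",
              mustWork = TRUE)
}

zero_noise <- function(seed = NULL)
  sim_config(ppm_jitter_sd = 0, dropout_supporting = 0, seed = seed)

panel_center <- function(id, panel = marker_panel()) {
  for (m in panel$markers) if (m$id == id) return(resolve_center(m))
  stop("no marker ", id)
}
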