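#' Read protein records from a FASTA file
#'
#' Parses UniProt-style (\code{sp|ACC|NAME}) or bare-identifier headers and an
#' optional \code{OS=} species field. Species can also be supplied (or
#' overridden) through \code{species_map}, a named character vector keyed by
#' accession. Sequences are validated against the 20 standard residues;
#' offending records are rejected with the file line number.
#'
#' @param path Path to a FASTA file.
#' @param species_map Optional named character vector: accession -> species.
#' @return A data.frame with columns \code{accession}, \code{species},
#'   \code{protein_name}, \code{sequence}, in file order.
#' @export
read_fasta <- function(path, species_map = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw_hdr <- grep("^>", raw)
  if (!length(raw_hdr)) stop("no FASTA records in ", path)
  nonblank <- which(nzchar(trimws(raw)))
  if (raw_hdr[1L] != nonblank[1L])
    stop(sprintf("malformed FASTA: sequence data before first header (line %d)",
                 nonblank[1L]))

  n <- length(raw_hdr)
  out <- vector("list", n)
  bounds <- c(raw_hdr, length(raw) + 1L)
  for (i in seq_len(n)) {
    hline <- raw[raw_hdr[i]]
    header <- sub("^>", "", hline)
    if (!nzchar(trimws(header)))
      stop(sprintf("malformed FASTA header at line %d: empty", raw_hdr[i]))
    first <- strsplit(trimws(header), "\\s+")[[1L]][1L]
    if (grepl("^(sp|tr)\\|", first)) {
      parts <- strsplit(first, "|", fixed = TRUE)[[1L]]
      if (length(parts) < 3L || !nzchar(parts[2L]))
        stop(sprintf("malformed UniProt header at line %d: '%s'",
                     raw_hdr[i], hline))
      accession <- parts[2L]
      protein_name <- parts[3L]
    } else {
      accession <- first
      protein_name <- first
    }
    species <- NA_character_
    os <- regmatches(header, regexpr("OS=[^=]*?(?=\\s+[A-Z]{2}=|$)",
                                     header, perl = TRUE))
    if (length(os)) species <- trimws(sub("^OS=", "", os))
    if (!is.null(species_map) && accession %in% names(species_map))
      species <- unname(species_map[[accession]])

    seq_lines <- if (raw_hdr[i] + 1L > bounds[i + 1L] - 1L) character(0) else
      raw[seq.int(raw_hdr[i] + 1L, bounds[i + 1L] - 1L)]
    seq_lines <- seq_lines[nzchar(trimws(seq_lines))]
    if (!length(seq_lines))
      stop(sprintf("record '%s' (line %d) has an empty sequence",
                   accession, raw_hdr[i]))
    seqs <- gsub("\\s", "", seq_lines)
    ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]*$", seqs)
    if (any(!ok)) {
      off <- which(!ok)[1L]
      stop(sprintf(
        "record '%s': non-standard residue in sequence at line %d",
        accession, raw_hdr[i] + off))
    }
    out[[i]] <- data.frame(
      accession = accession, species = species,
      protein_name = protein_name, sequence = paste(seqs, collapse = ""),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Digestion parameters
#'
#' Defaults mirror the standard "peptide mass" style in-silico digest used to
#' build the theoretical tables: monoisotopic MH+ values, up to 2 missed
#' cleavages, variable methionine oxidation, and the MALDI acquisition window
#' of 600-2000 Th.
#'
#' @param max_missed_cleavages Maximum internal K/R sites left uncleaved.
#' @param variable_met_oxidation Enumerate methionine-oxidation states?
#' @param mz_min,mz_max MH+ window in Th (inclusive).
#' @param max_ox_sites Peptides with more methionines than this enumerate only
#'   the unmodified and fully oxidized states (combinatorial cap).
#' @return An object of class \code{digest_params}.
#' @export
digest_params <- function(max_missed_cleavages = 2L,
                          variable_met_oxidation = TRUE,
                          mz_min = 600, mz_max = 2000,
                          max_ox_sites = 4L) {
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  stopifnot(max_missed_cleavages >= 0L, mz_min < mz_max, max_ox_sites >= 0L)
  structure(list(max_missed_cleavages = max_missed_cleavages,
                 variable_met_oxidation = isTRUE(variable_met_oxidation),
                 mz_min = mz_min, mz_max = mz_max,
                 max_ox_sites = as.integer(max_ox_sites)),
            class = "digest_params")
}

#' Tryptic cleavage sites
#'
#' Positions after which trypsin cleaves: C-terminal to K or R, suppressed
#' when the next residue is proline (Keil rule). The protein terminus is not a
#' site.
#'
#' @param sequence Residue string.
#' @return Integer positions (cleavage occurs between position i and i+1).
#' @examples
#' cleavage_sites("GRAKG") # 2, 4
#' cleavage_sites("AKAP")  # none: K before P suppressed
#' @export
cleavage_sites <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  i <- seq_len(n - 1L)
  i[chars[i] %in% c("K", "R") & chars[i + 1L] != "P"]
}

# all oxidation-state variants of one peptide sequence, honoring the cap
ox_variants <- function(sequence, params) {
  met <- which(strsplit(sequence, "", fixed = TRUE)[[1L]] == "M")
  if (!params$variable_met_oxidation || !length(met))
    return(list(integer(0)))
  if (length(met) > params$max_ox_sites) {
    warning(sprintf(
      "peptide '%s' has %d methionines (> cap %d): enumerating only the %s",
      sequence, length(met), params$max_ox_sites,
      "unmodified and fully oxidized states"), call. = FALSE)
    return(list(integer(0), met))
  }
  sets <- list(integer(0))
  for (m in met) sets <- c(sets, lapply(sets, function(s) c(s, m)))
  sets
}

#' Enumerate tryptic peptides of one protein
#'
#' Generates every cleavage product with 0..max missed cleavages, expands
#' variable methionine-oxidation states, computes MH+, and keeps entries
#' inside the m/z window. Repeated tryptic peptides within one protein are
#' emitted once per distinct (sequence, missed-cleavage, modification) triple.
#'
#' @param record One row of \code{read_fasta} output (or a list with
#'   \code{accession}, \code{species}, \code{sequence}).
#' @param params A \code{digest_params} object.
#' @param table Amino-acid table.
#' @return A data.frame with columns \code{accession}, \code{species},
#'   \code{sequence}, \code{oxidized_positions} (comma-separated, "" if none),
#'   \code{missed_cleavages}, \code{mz}.
#' @export
enumerate_peptides <- function(record, params = digest_params(),
                               table = amino_acid_table()) {
  seqstr <- record$sequence
  sites <- cleavage_sites(seqstr)
  n <- nchar(seqstr)
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  rows <- list(); k <- 0L
  for (si in seq_along(starts)) {
    for (mc in 0:params$max_missed_cleavages) {
      ei <- si + mc
      if (ei > length(ends)) break
      pep <- substr(seqstr, starts[si], ends[ei])
      for (ox in ox_variants(pep, params)) {
        # oxidation positions are peptide-local
        mz <- peptide_mz(peptide(pep, oxidized = ox, table = table),
                         table = table)
        if (mz < params$mz_min || mz > params$mz_max) next
        k <- k + 1L
        rows[[k]] <- data.frame(
          accession = record$accession, species = record$species,
          sequence = pep,
          oxidized_positions = paste(ox, collapse = ","),
          missed_cleavages = mc, mz = mz, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!k) {
    return(data.frame(accession = character(0), species = character(0),
                      sequence = character(0),
                      oxidized_positions = character(0),
                      missed_cleavages = integer(0), mz = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  unique(out)
}

#' Digest several proteins and annotate cross-species specificity
#'
#' Digests each record and annotates every peptide with the set of panel
#' species containing an identical sequence (comparison ignores modification
#' state and missed-cleavage count: sequence identity only). A peptide is
#' proteotypic when that set is a singleton.
#'
#' @param records data.frame from \code{read_fasta} (column \code{species}
#'   must be filled in).
#' @param params A \code{digest_params}.
#' @param table Amino-acid table.
#' @return An object of class \code{theoretical_table}: a data.frame sorted by
#'   \code{mz} with the \code{enumerate_peptides} columns plus
#'   \code{specificity} ("proteotypic" or "shared") and \code{shared_species}
#'   (comma-separated species carrying the sequence). Attributes store
#'   \code{params} and \code{panel_species}.
#' @export
digest_panel <- function(records, params = digest_params(),
                         table = amino_acid_table()) {
  if (any(is.na(records$species)))
    stop("every record needs a species label (use species_map in read_fasta)")
  per <- lapply(seq_len(nrow(records)),
                function(i) enumerate_peptides(records[i, ], params, table))
  annotate_specificity(do.call(rbind, per), params = params)
}

#' Annotate peptide specificity across a species panel
#'
#' @param entries data.frame of digest entries (as from
#'   \code{enumerate_peptides}, possibly row-bound across species).
#' @param params The \code{digest_params} used (stored as attribute).
#' @return A \code{theoretical_table} (see \code{\link{digest_panel}}).
#' @export
annotate_specificity <- function(entries, params = digest_params()) {
  if (!nrow(entries)) {
    entries$specificity <- character(0)
    entries$shared_species <- character(0)
  } else {
    seq_species <- tapply(entries$species, entries$sequence,
                          function(s) sort(unique(s)), simplify = FALSE)
    shared <- seq_species[entries$sequence]
    entries$shared_species <- vapply(shared, paste, "", collapse = ",")
    entries$specificity <- ifelse(lengths(shared) == 1L,
                                  "proteotypic", "shared")
    entries <- entries[order(entries$mz, entries$sequence), , drop = FALSE]
    rownames(entries) <- NULL
  }
  structure(entries, params = params,
            panel_species = sort(unique(entries$species)),
            class = c("theoretical_table", "data.frame"))
}

#' Write / read a theoretical peptide table (TSV)
#'
#' Tab-separated columns: accession, species, sequence, oxidized_positions,
#' missed_cleavages, mz, specificity, shared_species. A write -> read round
#' trip is the identity (m/z serialized at full precision).
#'
#' @param table A \code{theoretical_table}.
#' @param path File path.
#' @return \code{read_theoretical_table} returns a \code{theoretical_table};
#'   \code{write_theoretical_table} returns \code{path} invisibly.
#' @export
write_theoretical_table <- function(table, path) {
  df <- as.data.frame(table)
  cols <- c("accession", "species", "sequence", "oxidized_positions",
            "missed_cleavages", "mz", "specificity", "shared_species")
  df <- df[, cols, drop = FALSE]
  df$mz <- formatC(df$mz, format = "g", digits = 15)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_theoretical_table
#' @export
read_theoretical_table <- function(path) {
  if (!file.exists(path)) stop("no such table: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  need <- c("accession", "species", "sequence", "oxidized_positions",
            "missed_cleavages", "mz", "specificity", "shared_species")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("table missing columns: ", paste(miss, collapse = ", "))
  mz <- suppressWarnings(as.numeric(df$mz))
  if (anyNA(mz)) {
    stop(sprintf("non-numeric mz at data row %d", which(is.na(mz))[1L]))
  }
  mc <- suppressWarnings(as.integer(df$missed_cleavages))
  if (anyNA(mc) && nrow(df))
    stop(sprintf("non-integer missed_cleavages at data row %d",
                 which(is.na(mc))[1L]))
  df$mz <- mz
  df$missed_cleavages <- mc
  df[is.na(df$oxidized_positions), "oxidized_positions"] <- ""
  df[is.na(df$shared_species), "shared_species"] <- ""
  annotate_specificity(df[, setdiff(need, c("specificity", "shared_species"))])
}
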