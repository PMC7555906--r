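#' Monoisotopic amino-acid residue masses and mass-spectrometric constants
#'
#' Returns the lookup table used by all mass calculations in the package:
#' monoisotopic residue masses (Da) for the 20 standard amino acids, the mass
#' of water (added once per peptide), the proton mass (the default MALDI
#' adduct), the methionine-oxidation mass shift, and the CO / NH3 offsets that
#' relate the a/b/c fragment series.
#'
#' Isoleucine and leucine are distinct letters with identical mass: sequence
#' logic (e.g. species specificity) works on letters, mass logic on masses.
#'
#' @return An object of class \code{aa_table}: a list with elements
#'   \code{residues} (named numeric vector, Da), \code{water}, \code{proton},
#'   \code{oxidation}, \code{co}, \code{nh3} (all Da).
#' @examples
#' t <- amino_acid_table()
#' t$residues[["G"]]  # glycine residue, 57.021464 Da
#' @export
amino_acid_table <- function() {
  residues <- c(
    G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
    V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
    I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
    K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
    F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
  )
  structure(
    list(
      residues  = residues,
      water     = 18.010565,
      proton    = 1.007276,
      oxidation = 15.994915,
      co        = 27.994915,
      nh3       = 17.026549
    ),
    class = "aa_table"
  )
}

#' Construct a peptide
#'
#' A peptide is a residue string plus an optional set of positions carrying
#' variable methionine oxidation (+15.994915 Da each).
#'
#' @param sequence Single-letter residue string (standard 20 residues).
#' @param oxidized Integer positions of oxidized methionines (must index M).
#' @param table Amino-acid table used for validation.
#' @return An object of class \code{pmf_peptide}.
#' @examples
#' peptide("LLVVYPWTQR")
#' peptide("MK", oxidized = 1)
#' @export
peptide <- function(sequence, oxidized = integer(0), table = amino_acid_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("peptide sequence must be non-empty")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(table$residues))
  if (length(bad)) {
    stop(sprintf("unknown residue code '%s' at position %d in '%s'",
                 chars[bad[1L]], bad[1L], sequence))
  }
  oxidized <- sort(unique(as.integer(oxidized)))
  if (length(oxidized)) {
    if (any(oxidized < 1L | oxidized > length(chars)))
      stop("oxidized position out of range")
    if (any(chars[oxidized] != "M"))
      stop("oxidized positions must index methionine (M) residues")
  }
  structure(list(sequence = sequence, oxidized = oxidized),
            class = "pmf_peptide")
}

as_peptide <- function(p, table = amino_acid_table()) {
  if (inherits(p, "pmf_peptide")) p else peptide(p, table = table)
}

#' @export
print.pmf_peptide <- function(x, ...) {
  ox <- if (length(x$oxidized))
    sprintf(" [Mox at %s]", paste(x$oxidized, collapse = ",")) else ""
  cat(sprintf("<peptide> %s%s  MH+ %.3f\n", x$sequence, ox,
              peptide_mz(x)))
  invisible(x)
}

#' Monoisotopic neutral mass of a peptide
#'
#' Sum of residue masses plus one water, plus 15.994915 Da per oxidized
#' methionine.
#'
#' @param p A \code{pmf_peptide} or residue string.
#' @param table Amino-acid table.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' neutral_mass("G")           # 75.032 Da
#' neutral_mass("LLVVYPWTQR")  # 1273.718 Da
#' @export
neutral_mass <- function(p, table = amino_acid_table()) {
  p <- as_peptide(p, table)
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  sum(table$residues[chars]) + table$water +
    table$oxidation * length(p$oxidized)
}

#' m/z of a protonated (or adducted) peptide ion
#'
#' \code{(neutral mass + charge * adduct mass) / charge}. The default adduct
#' is a proton, so at charge 1 this is the MH+ value reported throughout.
#'
#' @param p Peptide (object or string).
#' @param charge Positive integer charge state.
#' @param adduct_mass Adduct mass in Da (default: proton).
#' @param table Amino-acid table.
#' @return m/z in Th.
#' @examples
#' peptide_mz("LLVVYPWTQR")                 # 1274.726
#' peptide_mz("LVSWYDNEFGYSNR", charge = 2) # 875.397
#' @export
peptide_mz <- function(p, charge = 1L, adduct_mass = NULL,
                       table = amino_acid_table()) {
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 1L) stop("charge must be a positive integer")
  if (is.null(adduct_mass)) adduct_mass <- table$proton
  (neutral_mass(p, table) + charge * adduct_mass) / charge
}

#' Signed relative mass error in parts per million
#'
#' \code{(observed - theoretical) / theoretical * 1e6}. Vectorized.
#'
#' @param observed Observed m/z (Th).
#' @param theoretical Theoretical m/z (Th); must be positive.
#' @return Signed ppm error.
#' @examples
#' ppm_error(1000.015, 1000) # +15 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0))
    stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Singly protonated fragment ion series
#'
#' Computes the a, b, c (N-terminal) or y (C-terminal) singly charged
#' monoisotopic fragment m/z values for a peptide of length n; each series has
#' n - 1 members. b and y obey \code{b_i + y_(n-i) = MH+ + proton}; a = b - CO;
#' c = b + NH3. Oxidized methionines contribute their shift to every fragment
#' containing them.
#'
#' @param p Peptide (object or string), length >= 2.
#' @param series One of \code{"a"}, \code{"b"}, \code{"c"}, \code{"y"}.
#' @param table Amino-acid table.
#' @return Numeric vector of fragment m/z, index 1 .. n-1.
#' @examples
#' fragment_series("GK", "y") # y1 = 147.113
#' @export
fragment_series <- function(p, series = c("a", "b", "c", "y"),
                            table = amino_acid_table()) {
  series <- match.arg(series)
  p <- as_peptide(p, table)
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) stop("fragment series require peptide length >= 2")
  res <- table$residues[chars]
  if (length(p$oxidized)) res[p$oxidized] <- res[p$oxidized] + table$oxidation
  res <- unname(res)
  prefix <- cumsum(res)[seq_len(n - 1L)]
  switch(series,
    b = prefix + table$proton,
    a = prefix + table$proton - table$co,
    c = prefix + table$proton + table$nh3,
    y = cumsum(rev(res))[seq_len(n - 1L)] + table$water + table$proton
  )
}

#' Nominal (integer) m/z
#'
#' Nearest integer to an m/z value; marker panels label peaks by nominal m/z
#' (e.g. 1750, 1764, 1593) while confirmation always happens at full ppm
#' precision.
#'
#' @param x Positive m/z value(s).
#' @return Integer vector.
#' @examples
#' nominal_mz(1749.787) # 1750
#' @export
nominal_mz <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) stop("m/z must be positive")
  as.integer(floor(x + 0.5))
}
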