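# Residue alphabet shared across the package.
#
# Residues are stored as single upper-case letters in the PAML ordering
# (A R N D C Q E G H I L K M F P S T W Y V), which is also the row/column
# order of the embedded JTT matrix.  GAP ("-") and UNKNOWN ("X") are the two
# missing-data states; both contribute all-ones partial likelihoods.

AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
GAP_CHAR <- "-"
UNKNOWN_CHAR <- "X"

# Ambiguity / non-standard codes collapsed to UNKNOWN on read.
AMBIGUOUS_CODES <- c("B", "Z", "J", "U", "O", "*", "?", ".")

#' Encode residues as integer states
#'
#' Maps single-letter residues to integer codes 1..20 in the package's
#' canonical ordering; gaps and unknowns become `NA` (missing data).
#'
#' @param x Character vector (or matrix) of single-letter residues.
#' @return Integer vector (or matrix) with `NA` for missing states.
#' @keywords internal
aa_encode <- function(x) {
  idx <- match(x, AA_STATES)
  if (is.matrix(x)) {
    idx <- matrix(idx, nrow = nrow(x), dimnames = dimnames(x))
  }
  idx
}

#' @keywords internal
aa_decode <- function(i) {
  out <- AA_STATES[i]
  out[is.na(i)] <- UNKNOWN_CHAR
  if (is.matrix(i)) out <- matrix(out, nrow = nrow(i), dimnames = dimnames(i))
  out
}

# Normalize raw characters from a sequence file: upper-case, map gap-like
# characters to GAP, ambiguity codes (and anything unrecognised) to UNKNOWN.
# Returns list(chars, n_mapped) where n_mapped counts out-of-alphabet cells.
normalize_residues <- function(x) {
  x <- toupper(x)
  x[x %in% c("-", "~")] <- GAP_CHAR
  known <- x %in% c(AA_STATES, GAP_CHAR, UNKNOWN_CHAR)
  n_mapped <- sum(!known)
  x[!known] <- UNKNOWN_CHAR
  list(chars = x, n_mapped = n_mapped)
}
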