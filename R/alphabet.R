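#' @useDynLib aacontext, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The 20 canonical amino acids
#'
#' One-letter codes of the canonical amino acids in alphabetical order.
#' This ordering is used for every count vector, frequency vector and
#' component column in the package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Placeholder for non-canonical residues
#'
#' Residues outside the 20 canonical one-letter codes (X, U, B, Z, O, *, .,
#' ...) are mapped to this symbol on input.  It occupies its position --
#' so coordinates and structure tracks stay aligned -- but is excluded
#' from all counts and frequency denominators.
#'
#' @format Character scalar.
#' @export
AA_UNKNOWN <- "?"

STRUCTURE_CLASSES <- c("H", "E", "C")

# Map a residue string to integer codes 1..20 (AA_ALPHABET order),
# 0 for the unknown symbol.  Assumes the string is already normalized.
aa_ints <- function(x) {
  v <- match(strsplit(x, "", fixed = TRUE)[[1]], AA_ALPHABET)
  v[is.na(v)] <- 0L
  v
}

# Upper-case and collapse every non-canonical character to AA_UNKNOWN.
# Returns the normalized string; the number of replacements is recorded
# in attr(, "n_replaced").
normalize_sequence <- function(x) {
  x <- toupper(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- !(ch %in% AA_ALPHABET)
  ch[bad] <- AA_UNKNOWN
  out <- paste0(ch, collapse = "")
  attr(out, "n_replaced") <- sum(bad & ch != AA_UNKNOWN | bad)
  attr(out, "n_replaced") <- sum(bad)
  out
}

is_canonical_aa <- function(a) {
  is.character(a) && length(a) == 1L && nchar(a) == 1L && a %in% AA_ALPHABET
}

# Empty named count vector over the canonical alphabet.
aa_zero_counts <- function() {
  stats::setNames(integer(length(AA_ALPHABET)), AA_ALPHABET)
}
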