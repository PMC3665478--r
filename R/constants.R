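# Residue alphabets and reference tables shared across the package.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter residue codes in fixed alphabetical order. This
#' order defines the index of every 20-element feature block (mutation
#' encoding, sequence environment, structural environment), so it is part of
#' the versioned feature layout.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Ambiguity codes tolerated in sequences but never counted as residues.
aa_ambiguity <- function() c("X", "B", "Z", "U")

aa_three_to_one_map <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' Translate residue codes between three- and one-letter conventions
#'
#' Unknown three-letter codes (modified or non-standard residues) translate to
#' `NA`.
#'
#' @param x Character vector of residue codes.
#' @return Character vector of the same length.
#' @export
aa_three_to_one <- function(x) {
  unname(aa_three_to_one_map[toupper(x)])
}

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) {
  m <- setNames(names(aa_three_to_one_map), aa_three_to_one_map)
  unname(m[toupper(x)])
}

#' Reference maximum accessible surface areas
#'
#' Theoretical per-residue maximum accessible surface areas (squared
#' angstroms) for an extended Gly-X-Gly tripeptide, used to normalise absolute
#' accessibility into relative solvent accessibility (RSA). The table follows
#' the widely used theoretical maxima of Tien et al. (2013). Any function that
#' consumes it accepts an alternative named vector, so the reference is
#' swappable without code changes.
#'
#' @return Named numeric vector over the 20 standard one-letter codes.
#' @export
max_asa_reference <- function() {
  c(A = 129, C = 167, D = 193, E = 223, F = 240,
    G = 104, H = 224, I = 197, K = 236, L = 201,
    M = 224, N = 195, P = 159, Q = 225, R = 274,
    S = 155, T = 172, V = 174, W = 285, Y = 263)
}

#' Saturating count scaling
#'
#' Maps an unbounded non-negative count onto `[0, 1)` via `n / (n + k)` so
#' that counts (alignment depth, number of GO terms, independent observation
#' counts) can enter a kernel classifier on the same scale as frequencies.
#'
#' @param n Non-negative numeric vector of counts.
#' @param k Saturation constant (default 100): the count at which the scaled
#'   value reaches 0.5.
#' @return Numeric vector in `[0, 1)`.
#' @export
scale_count <- function(n, k = 100) {
  stopifnot(is.numeric(n), all(is.finite(n)), all(n >= 0), k > 0)
  n / (n + k)
}
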