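#' @keywords internal
"_PACKAGE"

# 20 standard amino acids, one-letter codes, fixed ordering used as the
# sequence-motif axis of every count/potential table.
AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
         G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
         M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
         S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

AA3TO1 <- stats::setNames(names(AA3), AA3)

#' Convert three-letter residue codes to one-letter codes
#'
#' Only the 20 standard amino acids are recognized; anything else maps
#' to `NA`.
#'
#' @param x character vector of three-letter residue names (e.g. `"ALA"`).
#' @return character vector of one-letter codes, `NA` for non-standard.
#' @keywords internal
aa_three_to_one <- function(x) {
  unname(AA3TO1[toupper(x)])
}

# backbone atom names never counted as side-chain heavy atoms
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
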