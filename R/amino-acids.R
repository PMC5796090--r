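# Amino-acid alphabets, name conversion and bundled property scales.

#' One-letter codes of the 20 standard amino acids
#'
#' Alphabetical by one-letter code; the canonical ordering used for
#' property-distance matrices.
#' @export
AA_ONE <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

#' Convert between one- and three-letter amino-acid codes
#'
#' @param x character vector of codes (either case).
#' @return character vector of the converted codes.
#' @examples
#' aa_three_to_one("Thr")   # "T"
#' aa_one_to_three("R")     # "ARG"
#' @export
aa_three_to_one <- function(x) {
  m <- match(toupper(x), AA_THREE)
  if (anyNA(m)) abort("unknown three-letter amino-acid code: %s",
                      paste(x[is.na(m)], collapse = ", "))
  names(AA_THREE)[m]
}

#' @rdname aa_three_to_one
#' @export
aa_one_to_three <- function(x) {
  m <- match(toupper(x), names(AA_THREE))
  if (anyNA(m)) abort("unknown one-letter amino-acid code: %s",
                      paste(x[is.na(m)], collapse = ", "))
  unname(AA_THREE[m])
}

#' Formal side-chain charges at neutral pH
#'
#' +1 for Arg and Lys, -1 for Asp and Glu, 0 otherwise (His neutral).
#' @export
AA_CHARGE <- c(A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0, I = 0,
               K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0,
               T = 0, V = 0, W = 0, Y = 0)

#' Wimley-White interface hydrophobicity scale
#'
#' Experimentally determined free energies of transfer (kcal/mol) from
#' water to the POPC bilayer interface for residue X in Ac-WL-X-LL
#' pentapeptides; charged forms for D, E, K, R, neutral His. Positive
#' values disfavour the interface. Default hydrophobicity scale for the
#' property-distance metric; any named numeric vector over the 20
#' standard residues can be supplied instead.
#' @export
WIMLEY_WHITE_INTERFACE <- c(
  A = 0.17, C = -0.24, D = 1.23, E = 2.02, F = -1.13,
  G = 0.01, H = 0.17, I = -0.31, K = 0.99, L = -0.56,
  M = -0.23, N = 0.42, P = 0.45, Q = 0.58, R = 0.81,
  S = 0.13, T = 0.14, V = 0.07, W = -1.85, Y = -0.94)

#' Read a hydrophobicity scale from a two-column TSV (residue, value)
#'
#' @param path path to a headered TSV with columns `residue` and `value`
#'   (one-letter codes).
#' @return named numeric vector keyed by one-letter code.
#' @export
read_scale <- function(path) {
  d <- read_tsv(path)
  check_that(all(c("residue", "value") %in% names(d)),
             "scale file %s must have columns 'residue' and 'value'", path)
  stats::setNames(as.numeric(d$value), toupper(d$residue))
}
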