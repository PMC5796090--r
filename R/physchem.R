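# Property-distance (PD) metric between amino-acid types.
#
# Each residue type carries a two-component property vector
# (hydrophobicity H, formal charge Q); PD is the Euclidean distance
# between the two vectors. Hydrophobicity comes from a pluggable scale
# (Wimley-White interface values by default); charge is the integer
# formal charge (+1 R/K, -1 D/E, 0 otherwise).

#' Property vector of an amino-acid type
#'
#' @param aa one-letter residue code.
#' @param scale named numeric hydrophobicity scale keyed by one-letter code.
#' @return numeric c(hydrophobicity, charge).
#' @export
property_vector <- function(aa, scale = WIMLEY_WHITE_INTERFACE) {
  aa <- toupper(aa)
  check_that(length(aa) == 1L && aa %in% names(scale),
             "residue '%s' not present in the hydrophobicity scale", aa)
  check_that(aa %in% names(AA_CHARGE), "unknown residue symbol '%s'", aa)
  c(hydrophobicity = unname(scale[aa]), charge = unname(AA_CHARGE[aa]))
}

#' Property distance between two amino-acid types
#'
#' Euclidean distance between (hydrophobicity, charge) property vectors:
#' \deqn{PD(x,y) = \sqrt{(H(x)-H(y))^2 + (Q(x)-Q(y))^2}}
#' Symmetric, non-negative, zero iff the property vectors coincide, and a
#' true metric (it is the Euclidean metric on the property plane).
#'
#' @param x,y one-letter residue codes.
#' @param scale hydrophobicity scale, named numeric vector by one-letter code.
#' @return non-negative scalar.
#' @examples
#' pd("T", "M")            # Thr vs Met
#' pd("R", "K")            # equal charges: reduces to |H(R) - H(K)|
#' @export
pd <- function(x, y, scale = WIMLEY_WHITE_INTERFACE) {
  px <- property_vector(x, scale)
  py <- property_vector(y, scale)
  sqrt(sum((px - py)^2))
}

#' Full 20 x 20 property-distance matrix
#'
#' @param scale hydrophobicity scale, named numeric vector by one-letter code.
#' @param residues residue codes to include (default the 20 standard).
#' @return symmetric matrix with zero diagonal, dimnames = residues.
#' @export
pd_matrix <- function(scale = WIMLEY_WHITE_INTERFACE, residues = AA_ONE) {
  check_that(all(residues %in% names(scale)),
             "scale is missing residues: %s",
             paste(setdiff(residues, names(scale)), collapse = ", "))
  h <- scale[residues]
  q <- AA_CHARGE[residues]
  m <- sqrt(outer(h, h, "-")^2 + outer(q, q, "-")^2)
  dimnames(m) <- list(residues, residues)
  m
}

#' Write a property-distance matrix as TSV
#'
#' First column `residue`, remaining columns in amino-acid order.
#' @param m matrix from [pd_matrix()].
#' @param path output path.
#' @export
write_pd_matrix <- function(m, path) {
  d <- data.frame(residue = rownames(m), m, check.names = FALSE)
  write_tsv(d, path)
}
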