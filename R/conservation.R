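# Evolutionary conservation (EC) scores from a multiple sequence alignment.
#
# EC(i) = N_identity(i) / N_total: the fraction of aligned sequences whose
# residue at the alignment column of reference position i equals the
# reference residue. Scores are indexed by ungapped reference positions;
# columns where the reference itself is gapped carry no score.

#' Construct an alignment object
#'
#' @param sequences named character vector of equal-length gapped sequences
#'   (gap characters `-` or `.`).
#' @param reference_id name of the reference (e.g. human) row.
#' @return an object of class `msa_alignment`.
#' @export
alignment <- function(sequences, reference_id) {
  check_that(length(sequences) >= 1L, "alignment is empty")
  check_that(!is.null(names(sequences)) && !anyNA(names(sequences)),
             "sequences must be named")
  widths <- nchar(sequences)
  check_that(length(unique(widths)) == 1L,
             "alignment rows have unequal lengths (%s)",
             paste(unique(widths), collapse = ", "))
  check_that(reference_id %in% names(sequences),
             "reference '%s' not found among %d sequences",
             reference_id, length(sequences))
  sequences <- toupper(sequences)
  bad <- grepl("[^A-Z.*-]", sequences)
  check_that(!any(bad), "invalid characters in rows: %s",
             paste(names(sequences)[bad], collapse = ", "))
  structure(list(sequences = sequences, reference_id = reference_id),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("<msa_alignment> %d sequences x %d columns, reference '%s'\n",
              length(x$sequences), nchar(x$sequences[[1]]), x$reference_id))
  invisible(x)
}

#' Read a multiple sequence alignment from FASTA or Clustal
#'
#' Delegates parsing to Biostrings; the reference defaults to the first
#' record, matching the generator's convention of writing it first.
#'
#' @param path path to an aligned FASTA or Clustal file.
#' @param reference_id reference row id; default first sequence in the file.
#' @param format "fasta" or "clustal"; guessed from the extension when NULL
#'   (`.aln`/`.clustal` mean Clustal, anything else FASTA).
#' @return an `msa_alignment`.
#' @export
read_alignment <- function(path, reference_id = NULL, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(aln|clustal|clu)$", path, ignore.case = TRUE))
      "clustal" else "fasta"
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(aln)
  ids <- sub("\\s.*$", "", names(seqs))  # drop FASTA description
  names(seqs) <- ids
  alignment(seqs, reference_id %||% ids[[1L]])
}

GAP_CHARS <- c("-", ".")

#' Per-position evolutionary conservation score
#'
#' For every ungapped position of the reference row, the fraction of
#' alignment rows carrying the identical residue at that column. The
#' reference row is included in both numerator and denominator by default,
#' so scores lie in (0, 1]; gaps in non-reference rows count as
#' non-identical while still contributing to the denominator.
#'
#' @param aln an `msa_alignment`.
#' @param include_reference count the reference row itself (default TRUE).
#' @return `residue_profile` (named numeric) indexed by ungapped reference
#'   position, with the reference residues as attribute `reference_aa`.
#' @examples
#' a <- alignment(c(hum = "AKT", sp1 = "AKV", sp2 = "ART", sp3 = "VKT"), "hum")
#' ec_score(a)   # 0.75 0.75 0.75
#' @export
ec_score <- function(aln, include_reference = TRUE) {
  check_that(inherits(aln, "msa_alignment"), "not an msa_alignment")
  mat <- do.call(rbind, strsplit(unname(aln$sequences), ""))
  rownames(mat) <- names(aln$sequences)
  ref <- mat[aln$reference_id, ]
  keep <- !(ref %in% GAP_CHARS)
  check_that(any(keep), "reference row is entirely gaps")
  cols <- which(keep)
  counts <- colSums(mat[, cols, drop = FALSE] ==
                      matrix(ref[cols], nrow(mat), length(cols), byrow = TRUE))
  total <- nrow(mat)
  if (!include_reference) {
    counts <- counts - 1L   # reference always matches itself
    total <- total - 1L
    check_that(total > 0L, "alignment has only the reference row")
  }
  scores <- counts / total
  pos <- seq_along(cols)    # ungapped reference numbering, 1-based
  residue_profile(stats::setNames(scores, pos), units = "fraction",
                  extra = list(reference_aa = stats::setNames(ref[cols], pos)))
}

#' Mask of highly conserved positions
#'
#' Strict inequality: positions with score > threshold.
#'
#' @param profile a `residue_profile` of EC scores.
#' @param threshold conservation cutoff, default 0.9.
#' @return named logical vector over the profile's positions.
#' @export
conserved_mask <- function(profile, threshold = 0.9) {
  v <- as.numeric(profile)
  stats::setNames(v > threshold, names(profile))
}
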