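# Minimal PDB ATOM-record reader/writer and the structure container.
#
# No PDB engine ships with the installed R stack, so the fixed-width
# ATOM/HETATM format (columns per the wwPDB v3.3 specification) is parsed
# here directly. Only the fields the pipeline needs are kept.

#' Standard van der Waals radii by element (Angstrom)
#'
#' Bondi-style values; `default` is used for unknown elements.
#' @export
ELEMENT_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                   P = 1.80, default = 1.70)

#' Construct a structure model
#'
#' @param atoms data.frame with columns `residue` (1-based number),
#'   `resname`, `atom`, `x`, `y`, `z` (Angstrom), `element`, and optionally
#'   `radius`; missing radii are filled from `radii` by element.
#' @param membrane_slab numeric length-2 z-interval (Angstrom) of the
#'   membrane, or NULL for a soluble protein.
#' @param radii element-keyed radii used to fill missing values.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, membrane_slab = NULL,
                            radii = ELEMENT_RADII) {
  need <- c("residue", "resname", "atom", "x", "y", "z", "element")
  check_that(all(need %in% names(atoms)),
             "atoms must have columns: %s", paste(need, collapse = ", "))
  if (is.null(atoms$radius)) {
    idx <- match(atoms$element, names(radii))
    atoms$radius <- ifelse(is.na(idx), radii[["default"]], radii[idx])
  }
  check_that(all(atoms$radius > 0), "atomic radii must be positive")
  # numbering must be monotone non-decreasing within the (single) chain
  check_that(!is.unsorted(atoms$residue),
             "residue numbering is not monotone")
  if (!is.null(membrane_slab)) {
    check_that(is.numeric(membrane_slab) && length(membrane_slab) == 2L &&
                 membrane_slab[1] <= membrane_slab[2],
               "membrane_slab must be an ordered z-interval c(lo, hi)")
  }
  structure(list(atoms = atoms, membrane_slab = membrane_slab),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d residues%s\n",
              nrow(x$atoms), length(unique(x$atoms$residue)),
              if (is.null(x$membrane_slab)) "" else
                sprintf(", membrane z in [%.1f, %.1f] A",
                        x$membrane_slab[1], x$membrane_slab[2])))
  invisible(x)
}

#' Read a PDB file into a structure model
#'
#' Parses ATOM (and optionally HETATM) records only; a membrane slab can
#' be supplied directly or read from a sidecar line of the form
#' `REMARK 999 MEMBRANE Z <lo> <hi>` that [write_pdb()] emits.
#'
#' @param path path to a PDB file.
#' @param membrane_slab optional z-interval overriding any REMARK.
#' @param hetatm include HETATM records (default FALSE).
#' @return a `structure_model`.
#' @export
read_pdb <- function(path, membrane_slab = NULL, hetatm = FALSE) {
  lines <- readLines(path)
  pat <- if (hetatm) "^(ATOM  |HETATM)" else "^ATOM  "
  rec <- lines[grepl(pat, lines)]
  check_that(length(rec) > 0L, "no ATOM records in %s", path)
  fw <- function(l, a, b) trimws(substr(l, a, b))
  element <- fw(rec, 77, 78)
  # fall back to the first letter of the atom name when element is absent
  fallback <- sub("^[0-9]*", "", fw(rec, 13, 16))
  element <- ifelse(element == "", substr(fallback, 1, 1), element)
  atoms <- data.frame(
    residue = as.integer(fw(rec, 23, 26)),
    resname = fw(rec, 18, 20),
    atom    = fw(rec, 13, 16),
    x = as.numeric(fw(rec, 31, 38)),
    y = as.numeric(fw(rec, 39, 46)),
    z = as.numeric(fw(rec, 47, 54)),
    element = toupper(element),
    stringsAsFactors = FALSE)
  if (is.null(membrane_slab)) {
    mem <- lines[grepl("^REMARK 999 MEMBRANE Z", lines)]
    if (length(mem)) {
      v <- as.numeric(strsplit(trimws(sub("^REMARK 999 MEMBRANE Z", "", mem[1])),
                               "\\s+")[[1]])
      membrane_slab <- v[1:2]
    }
  }
  structure_model(atoms, membrane_slab = membrane_slab)
}

#' Write a structure model as PDB
#'
#' Emits fixed-width ATOM records plus, when a membrane slab is present,
#' a `REMARK 999 MEMBRANE Z lo hi` line that [read_pdb()] understands.
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  out <- character(0)
  if (!is.null(model$membrane_slab)) {
    out <- sprintf("REMARK 999 MEMBRANE Z %8.3f %8.3f",
                   model$membrane_slab[1], model$membrane_slab[2])
  }
  name4 <- ifelse(nchar(a$atom) < 4L, sprintf(" %-3s", a$atom),
                  substr(a$atom, 1, 4))
  out <- c(out, sprintf(
    "ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(a)), name4, a$resname, a$residue, a$x, a$y, a$z, a$element),
    "END")
  writeLines(out, path)
  invisible(path)
}
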