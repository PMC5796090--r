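# Per-residue scalar tracks (SASA, rSASA, EC, RMSF) share one container:
# a named numeric vector keyed by reference residue number, with a units
# annotation. Kept deliberately thin so profiles behave like plain vectors.

#' Per-residue scalar profile
#'
#' @param values named numeric vector; names are reference residue numbers.
#' @param units unit annotation, e.g. "A^2", "A", "fraction".
#' @param extra optional named list of additional attributes.
#' @return object of class `residue_profile` (a named numeric vector).
#' @export
residue_profile <- function(values, units = "", extra = NULL) {
  check_that(is.numeric(values), "profile values must be numeric")
  check_that(!is.null(names(values)), "profile values must be named by residue")
  structure(values, units = units, class = c("residue_profile", "numeric"),
            extra = extra)
}

#' @export
print.residue_profile <- function(x, ...) {
  cat(sprintf("<residue_profile> %d residues [%s]\n", length(x),
              attr(x, "units")))
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Residue numbers covered by a profile
#' @param profile a `residue_profile`.
#' @export
profile_residues <- function(profile) as.integer(names(profile))

#' Write a residue profile as a two-column TSV (residue, value)
#'
#' @param profile a `residue_profile`.
#' @param path output path.
#' @param value_col column name for the values (default "value").
#' @export
write_profile <- function(profile, path, value_col = "value") {
  d <- data.frame(residue = profile_residues(profile),
                  value = as.numeric(profile))
  names(d)[2L] <- value_col
  write_tsv(d, path)
}

#' Read a residue profile written by write_profile()
#'
#' @param path TSV with columns `residue` and one value column.
#' @param units unit annotation to attach.
#' @export
read_profile <- function(path, units = "") {
  d <- read_tsv(path)
  check_that("residue" %in% names(d) && ncol(d) >= 2L,
             "profile file %s must have columns residue,<value>", path)
  vcol <- setdiff(names(d), "residue")[1L]
  residue_profile(stats::setNames(as.numeric(d[[vcol]]), d$residue),
                  units = units)
}
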