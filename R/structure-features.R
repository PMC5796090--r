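# Membrane-aware solvent accessibility.
#
# Per-residue SASA by Shrake-Rupley sphere sampling, a geometric membrane
# slab that marks transmembrane residues as buried (SASA 0), and the
# relative SASA rSASA(i) = SASA(i) / SASA_max(type(i)) with the maximum
# taken from a free residue computed by the same engine.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Deterministic quasi-uniform points on the unit sphere (golden spiral)
#' @noRd
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue solvent accessible surface area (Shrake-Rupley)
#'
#' Places `n_points` quasi-uniform test points on each atom's solvent-
#' expanded sphere (radius + probe) and counts the points not occluded by
#' any neighbouring atom's expanded sphere; atom SASA is the accessible
#' fraction of the expanded-sphere area, and residue SASA sums its atoms.
#'
#' @param model a `structure_model`.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, water).
#' @param n_points test points per atom (default 960; must be >= 100).
#' @return `residue_profile` in Angstrom^2.
#' @export
sasa_per_residue <- function(model, probe_radius = 1.4, n_points = 960L) {
  check_that(inherits(model, "structure_model"), "not a structure_model")
  check_that(is_count(n_points) && n_points >= 100,
             "n_points must be an integer >= 100")
  check_that(is.numeric(probe_radius) && probe_radius >= 0,
             "probe_radius must be non-negative")
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (anyDuplicated(xyz)) {
    warning("structure contains atoms with identical coordinates",
            call. = FALSE)
  }
  expanded <- a$radius + probe_radius
  u <- sphere_points(n_points)
  area <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (expanded[i] + expanded)^2 & seq_along(d2) != i)
    ri <- expanded[i]
    if (length(nb) == 0L) {
      acc <- n_points
    } else {
      pts <- u * ri + matrix(xyz[i, ], n_points, 3L, byrow = TRUE)
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        free <- free & dj2 > expanded[j]^2
        if (!any(free)) break
      }
      acc <- sum(free)
    }
    area[i] <- 4 * pi * ri^2 * acc / n_points
  }
  per_res <- rowsum(area, a$residue)
  residue_profile(stats::setNames(as.numeric(per_res), rownames(per_res)),
                  units = "A^2")
}

#' Representative z-coordinate of each residue for the slab test
#'
#' Side-chain centroid z; falls back to the CA z for residues without
#' side-chain atoms (glycine, coarse models), then to the all-atom centroid.
#' @noRd
residue_ref_z <- function(model) {
  a <- model$atoms
  vapply(split(seq_len(nrow(a)), a$residue), function(idx) {
    side <- idx[!(a$atom[idx] %in% BACKBONE_ATOMS) &
                  !grepl("^H", a$atom[idx])]
    if (length(side)) return(mean(a$z[side]))
    ca <- idx[a$atom[idx] == "CA"]
    if (length(ca)) mean(a$z[ca]) else mean(a$z[idx])
  }, numeric(1))
}

#' Zero out SASA of residues buried in the membrane slab
#'
#' A residue is in the slab when its side-chain centroid z (CA z for
#' glycine) lies inside the model's membrane z-interval (inclusive);
#' those residues are treated as buried and their SASA is set to 0.
#' Models without a membrane slab pass through unchanged.
#'
#' @param profile `residue_profile` of SASA values (Angstrom^2).
#' @param model the `structure_model` the profile was computed from.
#' @return `residue_profile` with buried residues zeroed; attribute
#'   `buried` gives the residue numbers that were zeroed.
#' @export
apply_membrane_burial <- function(profile, model) {
  if (is.null(model$membrane_slab)) return(profile)
  zref <- residue_ref_z(model)
  slab <- model$membrane_slab
  buried_res <- names(zref)[zref >= slab[1] & zref <= slab[2]]
  v <- as.numeric(profile)
  names(v) <- names(profile)
  v[names(v) %in% buried_res] <- 0
  residue_profile(v, units = attr(profile, "units"),
                  extra = list(buried = as.integer(buried_res)))
}

#' Build a free Gly-X-Gly tripeptide in the coarse CA/CB representation
#'
#' Extended geometry: CA atoms 3.8 A apart along x, side-chain pseudo-atom
#' (CB) offset 1.5 A in z for non-glycine residues. Used to compute the
#' per-type maximum SASA with the same engine that scores the protein.
#' @param aa one-letter code of the centre residue.
#' @return a `structure_model` of 3 residues (no membrane).
#' @export
build_gxg_tripeptide <- function(aa) {
  aa <- toupper(aa)
  check_that(aa %in% AA_ONE, "unknown residue '%s'", aa)
  res <- c("G", aa, "G")
  rows <- list()
  for (k in 1:3) {
    rows[[length(rows) + 1L]] <- data.frame(
      residue = k, resname = AA_THREE[[res[k]]], atom = "CA",
      x = 3.8 * (k - 1), y = 0, z = 0, element = "C",
      stringsAsFactors = FALSE)
    if (res[k] != "G") {
      rows[[length(rows) + 1L]] <- data.frame(
        residue = k, resname = AA_THREE[[res[k]]], atom = "CB",
        x = 3.8 * (k - 1), y = 0, z = 1.5, element = "C",
        stringsAsFactors = FALSE)
    }
  }
  structure_model(do.call(rbind, rows))
}

#' Per-type maximum SASA reference table
#'
#' Maximum SASA of a free residue of each type: the centre residue of an
#' extended Gly-X-Gly tripeptide, scored with the same Shrake-Rupley
#' engine and parameters as the protein. Computing the reference with the
#' same engine removes engine bias from the rSASA ratio; a published
#' table can be supplied to [rsasa()] instead.
#'
#' @param probe_radius,n_points as in [sasa_per_residue()].
#' @param residues residue types to tabulate (default the 20 standard).
#' @return named numeric vector (Angstrom^2) keyed by one-letter code.
#' @export
sasa_max_table <- function(probe_radius = 1.4, n_points = 960L,
                           residues = AA_ONE) {
  vapply(residues, function(aa) {
    prof <- sasa_per_residue(build_gxg_tripeptide(aa),
                             probe_radius = probe_radius,
                             n_points = n_points)
    as.numeric(prof[["2"]])
  }, numeric(1))
}

#' Relative solvent accessible surface area
#'
#' rSASA(i) = SASA(i) / SASA_max(type(i)), clipped at 1 so sampling noise
#' above the free-residue reference cannot exceed the valid range.
#'
#' @param profile `residue_profile` of per-residue SASA (after any
#'   membrane-burial step).
#' @param model the `structure_model`, used to look up residue types.
#' @param max_table named numeric per-type maxima (one-letter codes);
#'   default computed by [sasa_max_table()] at the standard parameters.
#' @return dimensionless `residue_profile` in [0, 1].
#' @export
rsasa <- function(profile, model, max_table = NULL) {
  if (is.null(max_table)) max_table <- sasa_max_table()
  check_that(all(max_table > 0), "max SASA reference values must be positive")
  a <- model$atoms
  type3 <- vapply(split(a$resname, a$residue), function(r) r[[1]], "")
  type1 <- aa_three_to_one(type3[names(profile)])
  missing <- setdiff(unique(type1), names(max_table))
  check_that(length(missing) == 0L,
             "residue types absent from max SASA table: %s",
             paste(missing, collapse = ", "))
  v <- pmin(as.numeric(profile) / max_table[type1], 1)
  residue_profile(stats::setNames(v, names(profile)), units = "fraction")
}
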