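# Trajectory post-processing: per-residue RMSF, region-RMSF sums, the
# cumulative-RMSF pathogenicity discriminant, and residue cross-correlation
# (DCCM) difference maps.
#
# The cumulative statistic exploits a pattern seen across simulated DHCR7
# mutants: pathogenic mutations rigidify TM1, TM2 and CL2 and mobilize TM7
# and TM9-10, so TM1 + TM2 + CL2 - TM7 - TM9_10 separates the classes
# (> 50 A non-pathogenic-like, <= 46 A pathogenic-like, in between
# ambiguous).

#' DHCR7 topology regions
#'
#' Named inclusive residue intervals over the 475-residue human DHCR7
#' sequence: transmembrane helices TM1-TM8 and the merged TM9-10, cytosol
#' loops CL1-CL4, and the C-terminal domain. Residues outside every
#' interval (e.g. 1-39) belong to no region.
#'
#' @return named list of integer c(lo, hi) intervals.
#' @export
dhcr7_regions <- function() {
  list(TM1 = c(40L, 60L),  TM2 = c(94L, 115L),  TM3 = c(145L, 164L),
       TM4 = c(176L, 191L), TM5 = c(235L, 256L), TM6 = c(268L, 288L),
       TM7 = c(302L, 326L), TM8 = c(332L, 352L), TM9_10 = c(408L, 442L),
       CL1 = c(116L, 144L), CL2 = c(198L, 234L), CL3 = c(289L, 301L),
       CL4 = c(354L, 407L), CTD = c(443L, 475L))
}

#' Bundled reference region-RMSF table for DHCR7
#'
#' Region-RMSF sums (Angstrom) for wild-type DHCR7 and ten simulated
#' variants, from replicated membrane MD simulations reported in the
#' literature: five pathogenic (T154R, E288K, T289I, G303R, R404C),
#' three unknown-effect (V134L, R228Q, F361L) and two non-pathogenic
#' (R260Q, A452T) mutants. Columns: `variant`, `class`, the 14 region
#' sums, and `cumulative_printed`, the cumulative RMSF as printed in the
#' source table (its inputs are rounded to 0.1 A, so recomputation can
#' differ by up to 0.2 A).
#'
#' @return data.frame of 11 rows.
#' @export
dhcr7_region_rmsf_reference <- function() {
  read_tsv(system.file("extdata", "dhcr7_region_rmsf_reference.tsv",
                       package = "memtriage", mustWork = TRUE))
}

#' Validate a region map
#' @noRd
check_regions <- function(regions) {
  check_that(is.list(regions) && !is.null(names(regions)) &&
               !anyDuplicated(names(regions)),
             "regions must be a uniquely named list of intervals")
  for (nm in names(regions)) {
    iv <- regions[[nm]]
    check_that(length(iv) == 2L && iv[1] <= iv[2],
               "region %s: invalid interval", nm)
  }
  invisible(regions)
}

#' Optimal rotation superposing x onto y (Kabsch)
#' @noRd
kabsch_rotation <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF(i) = sqrt(mean over frames of |r_i(t) - <r_i>|^2), the fluctuation
#' of each residue's (C-alpha) position about its mean position. When
#' `superpose` is TRUE (default) every frame is first rigid-body fitted
#' (Kabsch) onto the first frame so global rotation/translation does not
#' inflate the fluctuations.
#'
#' @param ensemble numeric array frames x residues x 3 (Angstrom);
#'   dimnames on the residue axis supply residue numbers (default 1..n).
#' @param superpose remove rigid-body motion before measuring (default TRUE).
#' @return `residue_profile` in Angstrom.
#' @export
rmsf <- function(ensemble, superpose = TRUE) {
  check_that(is.array(ensemble) && length(dim(ensemble)) == 3L &&
               dim(ensemble)[3] == 3L,
             "ensemble must be a frames x residues x 3 array")
  nf <- dim(ensemble)[1]
  check_that(nf >= 2L, "RMSF needs at least 2 frames")
  nres <- dim(ensemble)[2]
  frames <- lapply(seq_len(nf), function(t) ensemble[t, , , drop = TRUE])
  if (nres == 1L) frames <- lapply(frames, function(f) matrix(f, 1L, 3L))
  if (superpose) {
    ref <- frames[[1]]
    refc <- sweep(ref, 2, colMeans(ref))
    frames <- lapply(frames, function(f) {
      fc <- sweep(f, 2, colMeans(f))
      fc %*% kabsch_rotation(fc, refc)
    })
  }
  arr <- simplify2array(frames)            # residues x 3 x frames
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- sweep(arr, c(1, 2), mean_pos)^2
  msf <- apply(dev2, 1, sum) / nf          # mean over frames of |dr|^2
  ids <- dimnames(ensemble)[[2]] %||% as.character(seq_len(nres))
  residue_profile(stats::setNames(sqrt(msf), ids), units = "A")
}

#' Region-RMSF: per-region sums of the residue profile
#'
#' Sum (not mean) of RMSF over the residues of each named region present
#' in the profile.
#'
#' @param profile `residue_profile` of RMSF values (Angstrom).
#' @param regions named list of inclusive intervals (default DHCR7 map).
#' @return named numeric vector of region sums (Angstrom).
#' @export
region_rmsf <- function(profile, regions = dhcr7_regions()) {
  check_regions(regions)
  res <- profile_residues(profile)
  vapply(names(regions), function(nm) {
    iv <- regions[[nm]]
    in_reg <- res >= iv[1] & res <= iv[2]
    check_that(any(in_reg), "region %s contains no residues of the profile",
               nm)
    sum(as.numeric(profile)[in_reg])
  }, numeric(1))
}

#' Cumulative-RMSF discriminant statistic
#'
#' TM1 + TM2 + CL2 - TM7 - TM9_10, in Angstrom.
#'
#' @param region_sums named numeric vector containing at least those five
#'   region sums (e.g. from [region_rmsf()]).
#' @return scalar (Angstrom).
#' @examples
#' cumulative_rmsf(c(TM1 = 18.2, TM2 = 18.3, CL2 = 65.1,
#'                   TM7 = 18.5, TM9_10 = 31.1))  # 52.0
#' @export
cumulative_rmsf <- function(region_sums) {
  need <- c("TM1", "TM2", "CL2", "TM7", "TM9_10")
  miss <- setdiff(need, names(region_sums))
  check_that(length(miss) == 0L, "missing region sums: %s",
             paste(miss, collapse = ", "))
  unname(region_sums[["TM1"]] + region_sums[["TM2"]] + region_sums[["CL2"]] -
           region_sums[["TM7"]] - region_sums[["TM9_10"]])
}

#' Classify a cumulative-RMSF value
#'
#' Values above the upper threshold look non-pathogenic, values at or
#' below the lower threshold look pathogenic, and the interval between
#' the thresholds is reported as ambiguous (the empirical rule states
#' both bounds but assigns nothing to the gap).
#'
#' @param cumulative cumulative RMSF (Angstrom); vectorized.
#' @param thresholds c(pathogenic = 46, nonpathogenic = 50): call is
#'   pathogenic_like when `<= thresholds["pathogenic"]` and
#'   nonpathogenic_like when `> thresholds["nonpathogenic"]`.
#' @return character vector in {"pathogenic_like", "nonpathogenic_like",
#'   "ambiguous"}.
#' @export
discriminant_call <- function(cumulative,
                              thresholds = c(pathogenic = 46,
                                             nonpathogenic = 50)) {
  check_that(thresholds[["pathogenic"]] <= thresholds[["nonpathogenic"]],
             "pathogenic threshold must not exceed the nonpathogenic one")
  ifelse(cumulative > thresholds[["nonpathogenic"]], "nonpathogenic_like",
         ifelse(cumulative <= thresholds[["pathogenic"]], "pathogenic_like",
                "ambiguous"))
}

#' Dynamic cross-correlation matrix of residue displacements
#'
#' C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>) over frames, with
#' dr the C-alpha displacement from the mean position. Symmetric, unit
#' diagonal, entries in [-1, 1], positive semidefinite.
#'
#' @param ensemble frames x residues x 3 array (Angstrom).
#' @param superpose rigid-body fit frames to the first frame (default TRUE).
#' @return residues x residues correlation matrix; residues with zero
#'   displacement variance yield NaN rows/columns with a warning.
#' @export
dccm <- function(ensemble, superpose = TRUE) {
  check_that(is.array(ensemble) && length(dim(ensemble)) == 3L &&
               dim(ensemble)[3] == 3L,
             "ensemble must be a frames x residues x 3 array")
  nf <- dim(ensemble)[1]
  check_that(nf >= 2L, "DCCM needs at least 2 frames")
  frames <- lapply(seq_len(nf), function(t) ensemble[t, , , drop = TRUE])
  if (superpose) {
    ref <- frames[[1]]
    refc <- sweep(ref, 2, colMeans(ref))
    frames <- lapply(frames, function(f) {
      fc <- sweep(f, 2, colMeans(f))
      fc %*% kabsch_rotation(fc, refc)
    })
  }
  arr <- simplify2array(frames)            # residues x 3 x frames
  mean_pos <- apply(arr, c(1, 2), mean)
  dev <- sweep(arr, c(1, 2), mean_pos)
  nres <- dim(arr)[1]
  # Gram matrix over frames and xyz: G = sum_t dev_t %*% t(dev_t)
  g <- matrix(0, nres, nres)
  for (t in seq_len(nf)) g <- g + tcrossprod(dev[, , t])
  v <- diag(g)
  if (any(v == 0)) {
    warning("residues with zero displacement variance: DCCM entries NaN",
            call. = FALSE)
  }
  c_mat <- g / sqrt(outer(v, v))
  ids <- dimnames(ensemble)[[2]] %||% as.character(seq_len(nres))
  dimnames(c_mat) <- list(ids, ids)
  c_mat
}

#' Mean-over-runs DCCM difference map (mutant minus wild type)
#'
#' Averages the per-run correlation matrices of the mutant and of the
#' wild type, then subtracts: positive entries mean motion more
#' correlated in the mutant. Antisymmetric under swapping the arguments.
#'
#' @param mutant_runs,wt_runs lists of frames x residues x 3 ensembles
#'   (or of precomputed DCCM matrices).
#' @param superpose passed to [dccm()] for raw ensembles.
#' @return difference matrix, same dimensions as the per-run DCCMs.
#' @export
dccm_difference <- function(mutant_runs, wt_runs, superpose = TRUE) {
  as_maps <- function(runs) {
    lapply(runs, function(r) {
      if (is.matrix(r)) r else dccm(r, superpose = superpose)
    })
  }
  avg <- function(maps) Reduce(`+`, maps) / length(maps)
  m <- avg(as_maps(mutant_runs))
  w <- avg(as_maps(wt_runs))
  check_that(all(dim(m) == dim(w)),
             "mutant and wild-type maps have different dimensions")
  m - w
}

#' Write a matrix (DCCM or difference map) as TSV with residue headers
#' @param m matrix with dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- data.frame(residue = rownames(m), m, check.names = FALSE)
  write_tsv(d, path)
}
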