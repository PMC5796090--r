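# MM/PBSA post-processing: frame selection, the nonpolar SASA term, and
# binding free energy aggregation.
#
# The PB electrostatics, internal and van der Waals terms arrive as
# per-frame inputs (table schema: time_ps, entity, internal, vdw,
# coulombic, pb_solv, sasa); this module only aggregates. Per frame,
#   G(entity) = internal + vdw + coulombic + pb_solv + (alpha*SASA + beta)
#   dG        = G(complex) - G(receptor) - G(ligand)
# and the run value is the mean over frames. Note the affine intercept
# beta is applied per entity per frame, so it contributes a constant
# -beta to every dG; `beta_per_entity = FALSE` drops that convention.

ENERGY_ENTITIES <- c("complex", "receptor", "ligand")
ENERGY_COMPONENTS <- c("internal", "vdw", "coulombic", "pb_solv")

#' Validate a per-frame energy table
#'
#' @param frames data.frame with columns time_ps, entity, internal, vdw,
#'   coulombic, pb_solv, sasa; one row per entity per frame.
#' @return the validated data.frame.
#' @export
validate_energy_frames <- function(frames) {
  need <- c("time_ps", "entity", ENERGY_COMPONENTS, "sasa")
  miss <- setdiff(need, names(frames))
  check_that(length(miss) == 0L, "energy table missing columns: %s",
             paste(miss, collapse = ", "))
  check_that(all(frames$entity %in% ENERGY_ENTITIES),
             "entity must be one of: %s", paste(ENERGY_ENTITIES, collapse = ", "))
  num <- c(ENERGY_COMPONENTS, "sasa", "time_ps")
  for (col in num) {
    check_that(all(is.finite(frames[[col]])),
               "non-finite values in column '%s'", col)
  }
  for (ent in unique(frames$entity)) {
    tt <- frames$time_ps[frames$entity == ent]
    check_that(all(diff(tt) > 0),
               "time_ps not strictly increasing for entity '%s'", ent)
  }
  frames
}

#' Select evenly spaced frames from the tail of a run
#'
#' Keeps the frames at `interval` spacing within the final `tail` window
#' of the run (timestamps tail_start + interval, ..., t_end), giving
#' exactly tail/interval frames — e.g. the last 10 ns of a 20 ns run at
#' 20 ps spacing yields 500 frames. Input sparser than the requested
#' interval is an error; nothing is interpolated.
#'
#' @param run energy data.frame (validated schema).
#' @param total_span expected full run length in ns (checked against the
#'   timestamps).
#' @param tail tail window in ns.
#' @param interval frame spacing in ps.
#' @return the selected rows.
#' @export
select_frames <- function(run, total_span = 20, tail = 10, interval = 20) {
  run <- validate_energy_frames(run)
  tail_ps <- tail * 1000
  n_frames <- tail_ps / interval
  check_that(abs(n_frames - round(n_frames)) < 1e-9,
             "interval (%g ps) must divide the tail window (%g ps) evenly",
             interval, tail_ps)
  n_frames <- round(n_frames)
  t_end <- max(run$time_ps)
  check_that(t_end >= total_span * 1000 - 1e-9,
             "run covers %.3f ns, expected at least %g ns",
             t_end / 1000, total_span)
  # match timestamps at fixed precision to dodge binary-fraction noise
  wanted <- round(t_end - interval * (rev(seq_len(n_frames)) - 1L), 6)
  have <- round(run$time_ps, 6)
  present <- wanted %in% have
  check_that(all(present),
             "input sparser than the %g ps interval: %d of %d tail frames missing",
             interval, sum(!present), length(wanted))
  out <- run[have %in% wanted, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nonpolar (SASA) solvation energy
#'
#' Affine surface-area model G_SASA = alpha * SASA + beta with the
#' widely used constants alpha = 0.0054 kcal/(mol A^2), beta = 0.92
#' kcal/mol.
#'
#' @param sasa solvent accessible surface area in Angstrom^2 (vectorized).
#' @param alpha,beta model constants.
#' @return energy in kcal/mol.
#' @export
nonpolar_sasa_energy <- function(sasa, alpha = 0.0054, beta = 0.92) {
  alpha * sasa + beta
}

#' Per-frame binding free energy and run mean
#'
#' @param frames energy data.frame covering all three entities at each
#'   timestamp (e.g. output of [select_frames()]).
#' @param alpha,beta nonpolar model constants.
#' @param beta_per_entity apply the beta intercept per entity (default
#'   TRUE, contributing -beta to every dG); FALSE drops beta entirely.
#' @return list(per_frame = data.frame(time_ps, dg), mean = scalar).
#' @export
binding_energy <- function(frames, alpha = 0.0054, beta = 0.92,
                           beta_per_entity = TRUE) {
  frames <- validate_energy_frames(frames)
  b <- if (beta_per_entity) beta else 0
  g <- rowSums(frames[, ENERGY_COMPONENTS]) +
    nonpolar_sasa_energy(frames$sasa, alpha, b)
  wide <- split(data.frame(time_ps = frames$time_ps, g = g), frames$entity)
  miss <- setdiff(ENERGY_ENTITIES, names(wide))
  check_that(length(miss) == 0L, "entities absent from table: %s",
             paste(miss, collapse = ", "))
  times <- wide$complex$time_ps
  for (ent in c("receptor", "ligand")) {
    check_that(identical(wide[[ent]]$time_ps, times),
               "timestamps of '%s' do not match the complex", ent)
  }
  dg <- wide$complex$g - wide$receptor$g - wide$ligand$g
  list(per_frame = data.frame(time_ps = times, dg = dg), mean = mean(dg))
}

#' Mean and sample standard deviation across independent runs
#'
#' @param run_means numeric vector of per-run binding energy means.
#' @return named numeric c(mean, sd); sd uses the n-1 denominator and is
#'   NA for a single run.
#' @export
run_statistics <- function(run_means) {
  check_that(is.numeric(run_means) && length(run_means) >= 1,
             "run_means must be a non-empty numeric vector")
  c(mean = mean(run_means), sd = stats::sd(run_means))
}

#' Read / write per-frame energy tables (TSV schema)
#' @param path TSV with columns time_ps, entity, internal, vdw, coulombic,
#'   pb_solv, sasa.
#' @export
read_energy_frames <- function(path) validate_energy_frames(read_tsv(path))

#' @rdname read_energy_frames
#' @param frames energy data.frame to write.
#' @export
write_energy_frames <- function(frames, path) write_tsv(frames, path)
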