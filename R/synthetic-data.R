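# Synthetic inputs with known ground truth for every pipeline stage:
# toy membrane helical bundles, MSAs with exact per-column identity,
# separable feature tables, region-shifted RMSF profiles, and per-frame
# MM/PBSA component tables. Every generator is deterministic under the
# spec seed (each draws from its own child stream, so generators can be
# called in any order).

#' Specification driving all synthetic-data generators
#'
#' @param seed integer master seed; fixed seed gives byte-identical outputs.
#' @param n_residues residues in the toy structure / reference sequence.
#' @param membrane_z_range z-interval of the membrane slab (Angstrom).
#' @param n_species rows in the toy alignment (reference included).
#' @param per_column_identity target identity fraction per alignment
#'   column, scalar or vector recycled over columns; achieved by exact
#'   count construction (rounded to the nearest achievable fraction).
#' @param n_pathogenic,n_nonpathogenic,n_unknown feature-table class sizes.
#' @param class_separation distance between class means in units of the
#'   per-feature SD (>= 0).
#' @param rmsf_region_effects named list: variant name -> named numeric of
#'   per-residue RMSF shifts (Angstrom) by region.
#' @param energy_means_sds nested list entity -> component -> c(mean, sd)
#'   (kcal/mol; sasa in Angstrom^2).
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       n_residues = 60L,
                       membrane_z_range = c(-15, 15),
                       n_species = 35L,
                       per_column_identity = 0.8,
                       n_pathogenic = 16L,
                       n_nonpathogenic = 23L,
                       n_unknown = 18L,
                       class_separation = 3,
                       rmsf_region_effects = default_rmsf_effects(),
                       energy_means_sds = default_energy_means_sds()) {
  check_that(is_count(seed), "seed must be an integer")
  check_that(is_count(n_residues) && n_residues > 0, "n_residues must be > 0")
  check_that(is.numeric(membrane_z_range) && length(membrane_z_range) == 2L &&
               membrane_z_range[1] <= membrane_z_range[2],
             "membrane_z_range must be an ordered interval")
  check_that(is_count(n_species) && n_species > 0, "n_species must be > 0")
  check_that(is_prob(per_column_identity),
             "per_column_identity must lie in [0,1]")
  for (nm in c("n_pathogenic", "n_nonpathogenic", "n_unknown")) {
    v <- get(nm)
    check_that(is_count(v) && v >= 0, "%s must be a non-negative count", nm)
  }
  check_that(is.numeric(class_separation) && class_separation >= 0,
             "class_separation must be >= 0")
  structure(list(seed = as.integer(seed), n_residues = as.integer(n_residues),
                 membrane_z_range = membrane_z_range,
                 n_species = as.integer(n_species),
                 per_column_identity = per_column_identity,
                 n_pathogenic = as.integer(n_pathogenic),
                 n_nonpathogenic = as.integer(n_nonpathogenic),
                 n_unknown = as.integer(n_unknown),
                 class_separation = class_separation,
                 rmsf_region_effects = rmsf_region_effects,
                 energy_means_sds = energy_means_sds),
            class = "synth_spec")
}

#' Default region-shift scenario: one pathogenic-like variant that
#' rigidifies TM1/TM2/CL2 and mobilizes TM7/TM9_10, one non-pathogenic-like
#' variant perturbing an uninvolved loop.
#' @rdname synth_spec
#' @export
default_rmsf_effects <- function() {
  list(mut_pathogenic = c(TM1 = -0.1, TM2 = -0.1, CL2 = -0.2,
                          TM7 = 0.1, TM9_10 = 0.1),
       mut_nonpathogenic = c(CL4 = 0.15))
}

#' Default per-entity MM/PBSA component means and SDs (kcal/mol; sasa A^2)
#' @rdname synth_spec
#' @export
default_energy_means_sds <- function() {
  list(
    complex  = list(internal = c(1200, 30), vdw = c(-150, 10),
                    coulombic = c(-2000, 50), pb_solv = c(-800, 40),
                    sasa = c(25000, 300)),
    receptor = list(internal = c(1150, 30), vdw = c(-120, 10),
                    coulombic = c(-1900, 50), pb_solv = c(-780, 40),
                    sasa = c(24000, 300)),
    ligand   = list(internal = c(50, 5), vdw = c(-5, 2),
                    coulombic = c(-80, 10), pb_solv = c(-60, 8),
                    sasa = c(900, 50)))
}

#' Read a generator spec from a JSON file
#'
#' Any field of [synth_spec()] may appear; missing fields take defaults.
#' @param path JSON path.
#' @return a `synth_spec`.
#' @export
read_synth_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(synth_spec))
  extra <- setdiff(names(j), known)
  check_that(length(extra) == 0L, "unknown spec fields: %s",
             paste(extra, collapse = ", "))
  do.call(synth_spec, j)
}

#' Toy transmembrane helical bundle with known burial ground truth
#'
#' Deterministic coarse-grained (CA + CB pseudo side chain) geometry:
#' transmembrane helices of 21 residues run vertically through the
#' membrane slab, alternating direction, connected by 9-residue loops
#' placed well outside the slab. Which residues are buried is therefore
#' known by construction (side-chain centroid z inside the slab).
#'
#' @param spec a `synth_spec` (needs n_residues >= 20).
#' @return list(model = `structure_model`, truth = data.frame(residue,
#'   buried)).
#' @export
make_toy_structure <- function(spec) {
  check_that(inherits(spec, "synth_spec"), "not a synth_spec")
  n <- spec$n_residues
  check_that(n >= 20L, "toy structure needs n_residues >= 20 (got %d)", n)
  slab <- spec$membrane_z_range
  helix_len <- 21L; loop_len <- 9L; period <- helix_len + loop_len
  rise <- 30 / (helix_len - 1)     # helix spans z in [-15, 15]
  loop_z <- 20                      # loops parked outside the default slab
  aas <- with_seed(child_seed(spec$seed, "structure"),
                   sample(AA_ONE, n, replace = TRUE))
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    seg <- (i - 1L) %/% period      # which helix+loop segment
    off <- (i - 1L) %% period
    going_up <- seg %% 2L == 0L
    ax <- 10 * seg                  # helix axes spaced 10 A apart in x
    if (off < helix_len) {          # transmembrane helix residue
      zi <- -15 + rise * off
      if (!going_up) zi <- -zi
      ang <- (100 * pi / 180) * off
      ca <- c(ax + 2.3 * cos(ang), 2.3 * sin(ang), zi)
      cb <- c(ax + 4.0 * cos(ang), 4.0 * sin(ang), zi)
    } else {                        # loop residue, outside the membrane
      j <- off - helix_len + 1L
      zl <- if (going_up) loop_z else -loop_z
      ca <- c(ax + 10 * j / (loop_len + 1), 6, zl)
      cb <- c(ax + 10 * j / (loop_len + 1), 6,
              zl + if (going_up) 1.5 else -1.5)
    }
    res3 <- AA_THREE[[aas[i]]]
    rows[[2L * i - 1L]] <- data.frame(
      residue = i, resname = res3, atom = "CA", x = ca[1], y = ca[2],
      z = ca[3], element = "C", stringsAsFactors = FALSE)
    if (aas[i] != "G") {
      rows[[2L * i]] <- data.frame(
        residue = i, resname = res3, atom = "CB", x = cb[1], y = cb[2],
        z = cb[3], element = "C", stringsAsFactors = FALSE)
    }
  }
  model <- structure_model(do.call(rbind, rows[!vapply(rows, is.null, TRUE)]),
                           membrane_slab = slab)
  zref <- residue_ref_z(model)
  truth <- data.frame(residue = as.integer(names(zref)),
                      buried = zref >= slab[1] & zref <= slab[2])
  rownames(truth) <- NULL
  list(model = model, truth = truth)
}

#' Toy MSA with exact per-column identity and known EC ground truth
#'
#' The reference row comes first; for each column the number of rows
#' matching the reference equals round(identity * n_species), clamped to
#' [1, n_species] (the reference always matches itself), so the EC ground
#' truth is exact by construction, not sampled.
#'
#' @param spec a `synth_spec` (needs n_species >= 2).
#' @return list(alignment = `msa_alignment`, ec_truth = `residue_profile`).
#' @export
make_toy_msa <- function(spec) {
  check_that(inherits(spec, "synth_spec"), "not a synth_spec")
  ns <- spec$n_species
  check_that(ns >= 2L, "toy MSA needs n_species >= 2 (got %d)", ns)
  n <- spec$n_residues
  p <- rep_len(spec$per_column_identity, n)
  with_seed(child_seed(spec$seed, "msa"), {
    ref <- sample(AA_ONE, n, replace = TRUE)
    mat <- matrix("", ns, n)
    mat[1L, ] <- ref
    k <- pmin(pmax(round(p * ns), 1L), ns)
    for (i in seq_len(n)) {
      match_rows <- if (k[i] > 1L) {
        c(1L, 1L + sample.int(ns - 1L, k[i] - 1L))
      } else 1L
      other <- sample(setdiff(AA_ONE, ref[i]), 1L)
      col <- rep(other, ns)
      col[match_rows] <- ref[i]
      mat[, i] <- col
    }
  })
  ids <- c("reference", sprintf("species_%02d", seq_len(ns - 1L)))
  seqs <- stats::setNames(apply(mat, 1L, paste0, collapse = ""), ids)
  aln <- alignment(seqs, "reference")
  truth <- residue_profile(stats::setNames(k / ns, seq_len(n)),
                           units = "fraction")
  list(alignment = aln, ec_truth = truth)
}

# Feature-space geometry shared by the generator and its documentation:
# class means sit at center +/- (separation/2) * direction * sd.
FEATURE_CENTER <- c(rsasa = 0.45, ec = 0.70, pd = 1.20)
FEATURE_SD     <- c(rsasa = 0.12, ec = 0.10, pd = 0.50)
FEATURE_DIRECTION <- c(rsasa = -1, ec = 1, pd = 1)  # pathogenic side

#' Labelled feature table with two separable classes plus unknowns
#'
#' Two Gaussians in (rsasa, ec, pd) space, truncated to the valid ranges:
#' the pathogenic class sits at low rSASA / high EC / high PD, the
#' non-pathogenic class mirrored, their means `class_separation` SDs
#' apart along each feature. Unknown rows are drawn from either class
#' with equal probability; their hidden true labels are returned in
#' `truth`. Non-discriminating ddg_mean/ddg_sd annotation columns are
#' included (same distribution in both classes).
#'
#' @param spec a `synth_spec`.
#' @return list(features = data.frame, truth = data.frame(mutation_id,
#'   true_label) for the unknown rows).
#' @export
make_feature_table <- function(spec) {
  check_that(inherits(spec, "synth_spec"), "not a synth_spec")
  sep <- spec$class_separation
  mu_p <- FEATURE_CENTER + (sep / 2) * FEATURE_DIRECTION * FEATURE_SD
  mu_n <- FEATURE_CENTER - (sep / 2) * FEATURE_DIRECTION * FEATURE_SD
  draw <- function(nrow, mu, ids) {
    m <- vapply(names(FEATURE_SD), function(f) {
      stats::rnorm(nrow, mu[[f]], FEATURE_SD[[f]])
    }, numeric(nrow))
    m <- matrix(m, nrow = nrow,
                dimnames = list(NULL, names(FEATURE_SD)))
    d <- as.data.frame(m)
    d$rsasa <- pmin(pmax(d$rsasa, 0), 1)
    d$ec <- pmin(pmax(d$ec, 1e-6), 1)
    d$pd <- pmax(d$pd, 0)
    cbind(data.frame(mutation_id = ids, stringsAsFactors = FALSE), d)
  }
  with_seed(child_seed(spec$seed, "features"), {
    path <- draw(spec$n_pathogenic, mu_p,
                 sprintf("P%03d", seq_len(spec$n_pathogenic)))
    nonp <- draw(spec$n_nonpathogenic, mu_n,
                 sprintf("N%03d", seq_len(spec$n_nonpathogenic)))
    hidden <- if (spec$n_unknown > 0) {
      sample(c("pathogenic", "non_pathogenic"), spec$n_unknown,
             replace = TRUE)
    } else character(0)
    unk <- do.call(rbind, lapply(seq_len(spec$n_unknown), function(i) {
      draw(1L, if (hidden[i] == "pathogenic") mu_p else mu_n,
           sprintf("U%03d", i))
    }))
    path$label <- rep("pathogenic", nrow(path))
    nonp$label <- rep("non_pathogenic", nrow(nonp))
    feats <- rbind(path, nonp)
    if (!is.null(unk)) {
      unk$label <- "unknown"
      feats <- rbind(feats, unk)
    }
    feats$ddg_mean <- stats::rnorm(nrow(feats), 0.5, 1.5)
    feats$ddg_sd <- abs(stats::rnorm(nrow(feats), 1.0, 0.5))
  })
  truth <- data.frame(mutation_id = sprintf("U%03d", seq_len(spec$n_unknown)),
                      true_label = hidden, stringsAsFactors = FALSE)
  list(features = feats, truth = truth)
}

# Wild-type per-residue RMSF means by region (Angstrom), the typical
# profile of a simulated polytopic membrane protein: transmembrane
# helices rigid (~0.7-0.9 A), cytosol loops mobile (~1.5-1.8 A), CTD in
# between. Chosen to match the replicated wild-type DHCR7 reference
# region sums bundled with the package.
WT_RMSF_PER_RESIDUE <- c(
  TM1 = 0.867, TM2 = 0.832, TM3 = 0.895, TM4 = 0.669, TM5 = 0.741,
  TM6 = 0.762, TM7 = 0.740, TM8 = 0.862, TM9_10 = 0.889,
  CL1 = 1.790, CL2 = 1.759, CL3 = 1.000, CL4 = 1.489, CTD = 1.145)

#' Per-residue RMSF profiles for WT and region-shifted mutants
#'
#' The wild-type profile is drawn once around region-typical baselines
#' (rigid transmembrane helices, mobile cytosol loops; unnamed residues
#' default to 1 A); each variant in `spec$rmsf_region_effects` equals WT
#' plus its stated additive shift on every residue of the named regions.
#' Ground-truth region sums for every profile are returned alongside.
#'
#' @param spec a `synth_spec`.
#' @param regions named list of inclusive intervals (default DHCR7 map).
#' @return list(profiles = named list of `residue_profile` ("WT" first),
#'   region_sums = matrix variants x regions).
#' @export
make_rmsf_profiles <- function(spec, regions = dhcr7_regions()) {
  check_that(inherits(spec, "synth_spec"), "not a synth_spec")
  check_regions(regions)
  n_res <- max(vapply(regions, `[`, integer(1), 2L))
  base <- rep(1, n_res)
  for (nm in intersect(names(regions), names(WT_RMSF_PER_RESIDUE))) {
    iv <- regions[[nm]]
    base[iv[1]:iv[2]] <- WT_RMSF_PER_RESIDUE[[nm]]
  }
  wt <- with_seed(child_seed(spec$seed, "rmsf"),
                  pmax(base + stats::rnorm(n_res, 0, 0.05), 0.05))
  profiles <- list(WT = residue_profile(
    stats::setNames(wt, seq_len(n_res)), units = "A"))
  for (nm in names(spec$rmsf_region_effects)) {
    eff <- spec$rmsf_region_effects[[nm]]
    bad <- setdiff(names(eff), names(regions))
    check_that(length(bad) == 0L, "variant %s shifts unknown regions: %s",
               nm, paste(bad, collapse = ", "))
    v <- wt
    for (rg in names(eff)) {
      iv <- regions[[rg]]
      idx <- iv[1]:iv[2]
      v[idx] <- pmax(v[idx] + eff[[rg]], 0)
    }
    profiles[[nm]] <- residue_profile(stats::setNames(v, seq_len(n_res)),
                                      units = "A")
  }
  sums <- t(vapply(profiles, region_rmsf, numeric(length(regions)),
                   regions = regions))
  list(profiles = profiles, region_sums = sums)
}

#' Per-frame MM/PBSA component series with closed-form ground truth
#'
#' Each component of each entity is drawn i.i.d. normal with the stated
#' (mean, SD); timestamps are uniform at `interval_ps` starting at
#' `interval_ps`. The ground-truth mean binding energy is the closed-form
#' combination of the component means (including alpha * SASA + beta per
#' entity).
#'
#' @param spec a `synth_spec`.
#' @param n_frames frames per entity.
#' @param interval_ps timestamp spacing (default 20 ps).
#' @param alpha,beta nonpolar-model constants used for the ground truth.
#' @return list(frames = data.frame (3 x n_frames rows), truth =
#'   list(dg_mean, dg_sd_per_frame)).
#' @export
make_energy_frames <- function(spec, n_frames = 500L, interval_ps = 20,
                               alpha = 0.0054, beta = 0.92) {
  check_that(inherits(spec, "synth_spec"), "not a synth_spec")
  check_that(is_count(n_frames) && n_frames >= 1, "n_frames must be >= 1")
  ms <- spec$energy_means_sds
  check_that(all(ENERGY_ENTITIES %in% names(ms)),
             "energy_means_sds must cover complex, receptor, ligand")
  times <- seq_len(n_frames) * interval_ps
  comps <- c(ENERGY_COMPONENTS, "sasa")
  frames <- with_seed(child_seed(spec$seed, "energy"), {
    do.call(rbind, lapply(ENERGY_ENTITIES, function(ent) {
      d <- data.frame(time_ps = times, entity = ent,
                      stringsAsFactors = FALSE)
      for (cp in comps) {
        p <- ms[[ent]][[cp]]
        check_that(length(p) == 2L && p[2] >= 0,
                   "energy_means_sds$%s$%s must be c(mean, sd>=0)", ent, cp)
        d[[cp]] <- stats::rnorm(n_frames, p[1], p[2])
      }
      d
    }))
  })
  gmean <- function(ent) {
    sum(vapply(ENERGY_COMPONENTS, function(cp) ms[[ent]][[cp]][1],
               numeric(1))) + alpha * ms[[ent]][["sasa"]][1] + beta
  }
  gvar <- function(ent) {
    sum(vapply(ENERGY_COMPONENTS, function(cp) ms[[ent]][[cp]][2]^2,
               numeric(1))) + alpha^2 * ms[[ent]][["sasa"]][2]^2
  }
  truth <- list(
    dg_mean = gmean("complex") - gmean("receptor") - gmean("ligand"),
    dg_sd_per_frame = sqrt(gvar("complex") + gvar("receptor") +
                             gvar("ligand")))
  list(frames = frames, truth = truth)
}
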