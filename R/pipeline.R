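# End-to-end orchestration: feature pipeline (structure + MSA + mutation
# list -> feature table -> KNN report) and dynamics pipeline (region-RMSF
# table or per-variant profiles -> cumulative-RMSF discriminant calls).
# Every run can write a manifest capturing config, seeds and package
# version for reproducibility.

#' Assemble (rSASA, EC, PD) feature vectors for a mutation table
#'
#' For each mutation (ref, position, alt): rSASA of the wild-type residue
#' at that position from the membrane-aware structure profile, EC score
#' at that position, and the property distance between the reference and
#' alternate residue types. Mutations whose position is absent from the
#' structure or the reference sequence (or whose stated reference residue
#' disagrees with it) are collected as per-row failures rather than
#' aborting the run.
#'
#' @param mutations data.frame with at least `id` and a `label` column
#'   (as from [classify_by_curation()] etc.), or any table with a
#'   `protein_change` column.
#' @param rsasa_profile `residue_profile` of rSASA values.
#' @param ec_profile `residue_profile` of EC scores (attribute
#'   `reference_aa` used to cross-check the stated reference residue).
#' @param scale hydrophobicity scale for PD.
#' @return list(features = data.frame(mutation_id, rsasa, ec, pd, label),
#'   failures = data.frame(mutation_id, reason)).
#' @export
build_feature_vectors <- function(mutations, rsasa_profile, ec_profile,
                                  scale = WIMLEY_WHITE_INTERFACE) {
  if (!all(c("id", "position", "ref", "alt") %in% names(mutations))) {
    pc <- parse_protein_change(mutations$protein_change)
    mutations <- cbind(pc, mutations[setdiff(names(mutations), names(pc))])
  }
  ref_aa <- attr(ec_profile, "extra")$reference_aa
  feats <- list(); fails <- list()
  for (i in seq_len(nrow(mutations))) {
    m <- mutations[i, ]
    pos <- as.character(m$position)
    reason <- NULL
    if (!pos %in% names(rsasa_profile)) {
      reason <- "position absent from structure"
    } else if (!pos %in% names(ec_profile)) {
      reason <- "position absent from reference sequence"
    } else if (!is.null(ref_aa) && !is.na(ref_aa[[pos]]) &&
               ref_aa[[pos]] != m$ref) {
      reason <- sprintf("reference residue mismatch (%s vs %s)",
                        m$ref, ref_aa[[pos]])
    }
    if (!is.null(reason)) {
      fails[[length(fails) + 1L]] <- data.frame(
        mutation_id = m$id, reason = reason, stringsAsFactors = FALSE)
      next
    }
    feats[[length(feats) + 1L]] <- data.frame(
      mutation_id = m$id,
      rsasa = as.numeric(rsasa_profile[[pos]]),
      ec = as.numeric(ec_profile[[pos]]),
      pd = pd(m$ref, m$alt, scale),
      label = if ("label" %in% names(m)) m$label else "unknown",
      stringsAsFactors = FALSE)
  }
  empty_feat <- data.frame(mutation_id = character(0), rsasa = numeric(0),
                           ec = numeric(0), pd = numeric(0),
                           label = character(0), stringsAsFactors = FALSE)
  empty_fail <- data.frame(mutation_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  list(features = if (length(feats)) do.call(rbind, feats) else empty_feat,
       failures = if (length(fails)) do.call(rbind, fails) else empty_fail)
}

#' Feature pipeline: structure + MSA + mutations -> KNN report
#'
#' @param config list with elements:
#'   `structure` (a `structure_model` or PDB path),
#'   `msa` (an `msa_alignment` or alignment path),
#'   `mutations` (data.frame with protein changes and labels),
#'   and optionally `k` (default 7), `train_n`, `seed` (default 1),
#'   `probe_radius`, `n_points`, `feature_set`, `out_dir`.
#' @return list(features, report, failures, sweep, manifest).
#' @export
run_feature_pipeline <- function(config) {
  model <- config$structure
  if (is.character(model)) model <- read_pdb(model)
  aln <- config$msa
  if (is.character(aln)) aln <- read_alignment(aln)
  check_that(!is.null(config$mutations), "config$mutations is required")

  sas <- sasa_per_residue(model,
                          probe_radius = config$probe_radius %||% 1.4,
                          n_points = config$n_points %||% 960L)
  sas <- apply_membrane_burial(sas, model)
  rsa <- rsasa(sas, model,
               max_table = config$max_sasa_table %||%
                 sasa_max_table(probe_radius = config$probe_radius %||% 1.4,
                                n_points = config$n_points %||% 960L))
  ec <- ec_score(aln)

  fv <- build_feature_vectors(config$mutations, rsa, ec)
  feats <- fv$features
  labelled <- feats[feats$label != "unknown", , drop = FALSE]
  unknowns <- feats[feats$label == "unknown", , drop = FALSE]
  seed <- config$seed %||% 1L
  k <- config$k %||% 7L
  feature_set <- config$feature_set %||% FEATURES_DEFAULT

  sweep_res <- NULL
  if (!is.null(config$train_n) && nrow(labelled) > config$train_n) {
    parts <- partition(labelled, config$train_n, seed)
    sweep_res <- k_sweep(parts$train, parts$test,
                         k_values = seq(1L, min(15L, nrow(parts$train))),
                         feature_set = feature_set)
    k <- sweep_res$recommended_k
  }
  report <- classify_unknowns(labelled, unknowns, k = k,
                              feature_set = feature_set)
  manifest <- run_manifest(config, seed)
  out <- list(features = feats, report = report, failures = fv$failures,
              sweep = sweep_res, k = k, manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' Dynamics pipeline: region-RMSF inputs -> discriminant report
#'
#' Input is either a table of per-variant region sums (`region_table`: a
#' data.frame or TSV path whose first column names the variant and whose
#' remaining columns are region sums) or a named list of per-residue RMSF
#' profiles (`profiles`), which are reduced with [region_rmsf()] first.
#'
#' @param config list with `region_table` or `profiles`, optional
#'   `regions` (default DHCR7 map), `thresholds`, `out_dir`.
#' @return list(report = data.frame(variant, <regions>, cumulative, call),
#'   manifest).
#' @export
run_dynamics_pipeline <- function(config) {
  regions <- config$regions %||% dhcr7_regions()
  if (!is.null(config$profiles)) {
    sums <- t(vapply(config$profiles, region_rmsf,
                     numeric(length(regions)), regions = regions))
    tab <- data.frame(variant = names(config$profiles), sums,
                      check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    tab <- config$region_table
    check_that(!is.null(tab), "config needs region_table or profiles")
    if (is.character(tab)) tab <- read_tsv(tab)
    names(tab)[1L] <- "variant"
  }
  if (nrow(tab) == 0L) {
    report <- cbind(tab, data.frame(cumulative = numeric(0),
                                    call = character(0)))
  } else {
    cum <- apply(tab[, -1L, drop = FALSE], 1L, function(r) {
      cumulative_rmsf(stats::setNames(as.numeric(r), names(tab)[-1L]))
    })
    report <- cbind(tab, data.frame(
      cumulative = as.numeric(cum),
      call = discriminant_call(as.numeric(cum),
                               thresholds = config$thresholds %||%
                                 c(pathogenic = 46, nonpathogenic = 50)),
      stringsAsFactors = FALSE))
  }
  manifest <- run_manifest(config, config$seed %||% NA)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(report, file.path(config$out_dir, "dynamics_report.tsv"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  list(report = report, manifest = manifest)
}

#' Manifest describing a run: serialized config, seed, version, hash
#' @noRd
run_manifest <- function(config, seed) {
  serializable <- lapply(config, function(x) {
    if (is.data.frame(x) || is.character(x) || is.numeric(x) ||
        is.logical(x) || is.list(x) && !is.object(x)) x else class(x)[1]
  })
  cfg_json <- jsonlite::toJSON(serializable, auto_unbox = TRUE, force = TRUE,
                               digits = NA)
  f <- tempfile(fileext = ".json")
  writeLines(as.character(cfg_json), f)
  h <- unname(tools::md5sum(f))
  unlink(f)
  list(package = "memtriage",
       version = as.character(utils::packageVersion("memtriage")),
       seed = seed,
       config = serializable,
       config_md5 = h)
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(out$features, file.path(dir, "features.tsv"))
  write_tsv(out$report, file.path(dir, "classification_report.tsv"))
  if (nrow(out$failures)) {
    write_tsv(out$failures, file.path(dir, "failures.tsv"))
  }
  if (!is.null(out$sweep)) {
    write_tsv(out$sweep$accuracy, file.path(dir, "k_sweep.tsv"))
  }
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(dir)
}
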