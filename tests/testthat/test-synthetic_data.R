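# Generators: construction guarantees, determinism, ground-truth
# self-consistency.

test_that("toy structure: burial ground truth holds by construction", {
  sp <- synth_spec(seed = 1, n_residues = 60)
  st <- make_toy_structure(sp)
  expect_equal(length(unique(st$model$atoms$residue)), 60L)
  expect_gte(sum(st$truth$buried), 10L)
  expect_gt(sum(!st$truth$buried), 0L)
  # slab membership of the emitted labels matches the geometry
  z <- memtriage:::residue_ref_z(st$model)
  slab <- st$model$membrane_slab
  expect_equal(unname(z >= slab[1] & z <= slab[2]), st$truth$buried)

  # slab covering all z buries everything
  st_all <- make_toy_structure(synth_spec(seed = 1, n_residues = 60,
                                          membrane_z_range = c(-1e6, 1e6)))
  expect_true(all(st_all$truth$buried))

  expect_error(make_toy_structure(synth_spec(seed = 1, n_residues = 19)),
               "n_residues")
})

test_that("toy structure round-trips through PDB byte-identically", {
  sp <- synth_spec(seed = 3, n_residues = 40)
  st <- make_toy_structure(sp)
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_pdb(st$model, f1)
  write_pdb(make_toy_structure(sp)$model, f2)  # same seed -> same file
  expect_identical(readLines(f1), readLines(f2))
  back <- read_pdb(f1)
  expect_equal(back$atoms$x, st$model$atoms$x, tolerance = 1e-3)
  expect_equal(back$membrane_slab, st$model$membrane_slab)
  expect_equal(back$atoms$residue, st$model$atoms$residue)
})

test_that("toy MSA achieves exact column identities", {
  # 4 species at 0.75 -> exactly 3 matches per column
  sp <- synth_spec(seed = 2, n_residues = 30, n_species = 4,
                   per_column_identity = 0.75)
  ms <- make_toy_msa(sp)
  mat <- do.call(rbind, strsplit(unname(ms$alignment$sequences), ""))
  ref <- mat[1, ]
  matches <- colSums(mat == matrix(ref, 4, 30, byrow = TRUE))
  expect_true(all(matches == 3L))
  expect_equal(as.numeric(ms$ec_truth), rep(0.75, 30))

  # identity 1 -> EC truth all 1
  ms1 <- make_toy_msa(synth_spec(seed = 2, n_residues = 10, n_species = 6,
                                 per_column_identity = 1))
  expect_equal(as.numeric(ms1$ec_truth), rep(1, 10))

  # determinism and preconditions
  expect_identical(make_toy_msa(sp), make_toy_msa(sp))
  expect_error(make_toy_msa(synth_spec(seed = 1, n_species = 1)),
               "n_species")
  expect_error(synth_spec(per_column_identity = 1.2), "per_column_identity")
})

test_that("feature table: sizes, separation scaling, hidden truth", {
  sp <- synth_spec(seed = 5, class_separation = 3)
  ft <- make_feature_table(sp)
  expect_equal(as.integer(table(ft$features$label)[c("pathogenic",
                                                     "non_pathogenic",
                                                     "unknown")]),
               c(16L, 23L, 18L))
  expect_equal(nrow(ft$truth), 18L)
  expect_true(all(ft$truth$true_label %in% c("pathogenic", "non_pathogenic")))

  # separation 3: classes linearly separable along the class-mean axis
  lab <- ft$features[ft$features$label != "unknown", ]
  x <- scale(as.matrix(lab[, c("rsasa", "ec", "pd")]))
  mu_p <- colMeans(x[lab$label == "pathogenic", ])
  mu_n <- colMeans(x[lab$label == "non_pathogenic", ])
  proj <- x %*% (mu_p - mu_n)
  expect_gt(min(proj[lab$label == "pathogenic"]),
            max(proj[lab$label == "non_pathogenic"]))

  # separation 0: class-conditional means equal within sampling error
  ft0 <- make_feature_table(synth_spec(seed = 5, class_separation = 0,
                                       n_pathogenic = 200,
                                       n_nonpathogenic = 200))
  f0 <- ft0$features
  for (f in c("rsasa", "ec", "pd")) {
    se <- sqrt(var(f0[[f]][f0$label == "pathogenic"]) / 200 +
                 var(f0[[f]][f0$label == "non_pathogenic"]) / 200)
    expect_lt(abs(mean(f0[[f]][f0$label == "pathogenic"]) -
                    mean(f0[[f]][f0$label == "non_pathogenic"])), 3.5 * se)
  }
})

test_that("rmsf profiles: shifts are region-exact and sums self-consistent", {
  regions <- dhcr7_regions()
  sp <- synth_spec(seed = 9,
                   rmsf_region_effects = list(mutA = c(TM7 = 0.5)))
  rp <- make_rmsf_profiles(sp, regions)
  wt <- as.numeric(rp$profiles$WT)
  mut <- as.numeric(rp$profiles$mutA)
  tm7 <- regions$TM7[1]:regions$TM7[2]
  expect_equal(mut[tm7], wt[tm7] + 0.5)
  expect_equal(mut[-tm7], wt[-tm7])
  expect_equal(rp$region_sums["mutA", "TM7"],
               rp$region_sums["WT", "TM7"] + 0.5 * length(tm7))

  # zero shifts -> mutant identical to WT
  rp0 <- make_rmsf_profiles(synth_spec(
    seed = 9, rmsf_region_effects = list(null_mut = numeric(0))))
  expect_equal(as.numeric(rp0$profiles$null_mut),
               as.numeric(rp0$profiles$WT))

  # emitted region sums match brute-force summation
  for (nm in rownames(rp$region_sums)) {
    v <- as.numeric(rp$profiles[[nm]])
    brute <- vapply(regions, function(iv) sum(v[iv[1]:iv[2]]), numeric(1))
    expect_equal(unname(rp$region_sums[nm, names(regions)]), unname(brute))
  }

  # shifts pushing the statistic below threshold flag pathogenic;
  # expected value by direct arithmetic on the emitted WT sums
  eff <- c(TM1 = -0.3, TM2 = -0.3, CL2 = -0.3)
  rp2 <- make_rmsf_profiles(synth_spec(seed = 9,
                                       rmsf_region_effects = list(m = eff)))
  widths <- vapply(regions[names(eff)], function(iv) diff(iv) + 1L,
                   integer(1))
  expected <- cumulative_rmsf(rp2$region_sums["WT", ]) +
    sum(eff * widths)
  expect_equal(cumulative_rmsf(rp2$region_sums["m", ]), expected)
  expect_identical(discriminant_call(expected), "pathogenic_like")
})

test_that("energy frames: shape, determinism, SD=0 exactness", {
  sp <- synth_spec(seed = 11)
  ef <- make_energy_frames(sp, n_frames = 500)
  expect_equal(nrow(ef$frames), 3L * 500L)
  expect_equal(as.integer(table(ef$frames$entity)), rep(500L, 3))
  expect_identical(make_energy_frames(sp, n_frames = 500), ef)

  # degenerate SD=0: run mean equals the closed-form truth exactly
  ms0 <- default_energy_means_sds()
  for (ent in names(ms0)) for (cp in names(ms0[[ent]])) {
    ms0[[ent]][[cp]][2] <- 0
  }
  ef0 <- make_energy_frames(synth_spec(seed = 11, energy_means_sds = ms0),
                            n_frames = 50)
  be0 <- binding_energy(ef0$frames)
  expect_equal(be0$mean, ef0$truth$dg_mean)
})
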