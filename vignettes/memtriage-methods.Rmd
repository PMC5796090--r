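---
title: "Methods: triaging membrane-protein missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triaging membrane-protein missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtriage)
```

## The problem

DHCR7, the 475-residue ER-membrane sterol reductase deficient in
Smith-Lemli-Opitz syndrome, carries dozens of reported missense variants
whose clinical effect is unknown. memtriage implements a triage pipeline
for this setting: cheap per-mutation biophysical features feed a
k-nearest-neighbour classifier, and, for variants subjected to molecular
dynamics, trajectory-derived discriminants (region-wise RMSF, residue
cross-correlation, MM/PBSA binding energies) provide independent
evidence. Everything downstream of an MD engine is in scope; running MD,
homology modelling, PB solvers and ΔΔG webservers are not — their
outputs enter as tables.

## Features

**Membrane-aware rSASA.** Per-residue solvent accessibility is computed
by Shrake–Rupley sampling: `n_points` quasi-uniform points (golden
spiral) on each atom's probe-expanded sphere, a point being accessible
when no neighbouring expanded sphere covers it. Defaults: probe 1.4 Å
(water), 960 points/atom — relative discretization error against a
10,000-point oracle is under 2% on the toy structures. The membrane is a
geometric z-slab: residues whose side-chain centroid z (Cα for glycine)
lies inside the slab are set to SASA 0 before normalization, so
transmembrane residues count as buried regardless of geometric exposure
to the (absent) lipid. The residue-level burial rule is this package's
choice; the source analysis only states that transmembrane residues were
treated as buried. Relative SASA is `SASA(i)/SASA_max(type)`, clipped to
[0, 1]; `SASA_max` is computed on extended Gly-X-Gly tripeptides *with
the same engine and parameters*, which cancels engine bias in the ratio.
A published per-type table can be supplied instead.

**EC score.** For each ungapped position of the reference row of an MSA,
the fraction of rows carrying the identical residue. Two conventions
were genuinely open: (1) the reference row counts in numerator and
denominator (default, so scores lie in (0, 1]; `include_reference =
FALSE` switches to the other reading, which differs by at most 1/n); (2)
gaps in non-reference rows count as mismatches while still contributing
to the denominator — the conservative reading of "species sharing the
identical residue". Comparison is case-insensitive.

**Property distance.** Each residue type is a point
(hydrophobicity, formal charge) and `pd(x, y)` is the Euclidean distance
between the two points. The printed source formula has a minus sign
between the squared terms, which can produce imaginary values and
contradicts its own description as a Euclidean distance; this package
implements the plus-sign Euclidean form. The hydrophobicity scale is
pluggable; the bundled default is the Wimley–White interface scale
(kcal/mol, charged D/E/K/R, neutral His), chosen because the source
cites an experimentally determined scale without printing values.
Absolute PD values therefore depend on the scale; only structural
properties (symmetry, zero diagonal, metric axioms, charge-pair
ordering) are asserted in tests.

## Classification

Plain KNN, because the feature space is three-dimensional and the
labelled set tiny (16 + 23). Features are z-scored with parameters fit
on the training split (the source is silent; unscaled features mix
fractions with kcal/mol — a flag disables it, and predictions are
affine-invariant when it is on). Euclidean distance; majority vote; tied
votes resolved by the single nearest neighbour, making even k
deterministic. `k_sweep()` reports accuracy per k and recommends the
median of the accuracy-maximizing set (upper-middle element for
even-sized sets), reproducing the published choice K = 7 for an argmax
set of {5..9}. The published 100% test accuracy depends on an
unpublished 39-mutation feature table and the unstated random split, so
it is not asserted anywhere; the classifier is instead validated against
exhaustive-distance oracles and on separable synthetic sets.

## Dynamics discriminants

Region-RMSF is the **sum** (not mean) of per-residue RMSF over each
named region of the bundled DHCR7 topology (TM1 40–60 … CTD 443–475,
inclusive, 1-based; residues outside every region count nowhere; TM9-10
is one merged interval as published). The cumulative statistic is
TM1 + TM2 + CL2 − TM7 − TM9_10: pathogenic mutants rigidify the first
group and mobilize the second. Calls: > 50 Å non-pathogenic-like,
≤ 46 Å pathogenic-like; the published rule states both bounds but never
assigns (46, 50], which this package reports explicitly as "ambiguous"
rather than silently folding it into either class.

RMSF itself is computed about the mean structure over frames, after
optional (default on) Kabsch superposition onto the first frame. DCCM
uses Cα displacement vectors:
`C_ij = <dr_i · dr_j> / sqrt(<|dr_i|²><|dr_j|²>)`; difference maps
average per-run DCCMs for mutant and wild type before subtracting.
Zero-variance residues give NaN entries with a warning rather than an
error, since frozen atoms are legitimate in restrained runs.

Whether the published per-region values are averages over the three
runs is unstated; this package averages when several runs are supplied.

## MM/PBSA

Frames are taken at a fixed interval from the tail window of a run
(default 20 ps over the last 10 ns of 20 ns → 500 frames); input sparser
than the interval is an error, never interpolated. Per frame and entity,
G = internal + vdW + Coulombic + PB solvation + (α·SASA + β) with
α = 0.0054, β = 0.92 kcal/mol, and ΔG = G(complex) − G(receptor) −
G(ligand). The β intercept is applied per entity per frame — the
standard convention, contributing a constant −β to every ΔG; the source
does not address the bookkeeping, so `beta_per_entity = FALSE` exposes
the other convention. Across independent runs the sample (n−1) SD is
reported; the estimator is likewise unstated in the source. No entropy
terms.

## Synthetic data: what it emulates, what it does not

Generators are deterministic per seed (each on its own child stream) and
emit their own ground truth:

* **Structures** — coarse CA + CB pseudo-side-chain helical bundles:
  21-residue vertical helices spanning the default ±15 Å slab,
  9-residue loops parked at |z| = 20 Å. Burial truth follows from the
  same centroid rule the pipeline uses. No lipids, no full side chains —
  SASA magnitudes are not protein-realistic, but ratios and burial logic
  are exercised faithfully.
* **MSAs** — per-column identity achieved by exact count construction
  (round(p·n), clamped to [1, n]), not Bernoulli sampling, so EC truth
  is exact, matching the published setting of 35 species.
* **Feature tables** — two Gaussians in (rSASA, EC, PD), truncated to
  valid ranges, means `class_separation` SDs apart per feature with the
  pathogenic class at low rSASA / high EC / high PD (the qualitative
  pattern reported for DHCR7); defaults 16 + 23 labelled + 18 unknown.
  ΔΔG columns are deliberately non-informative noise, mirroring the
  published finding that ΔΔG fails to discriminate. A green KNN test
  shows the classifier works on data matching its assumptions — not
  that real mutations are this cleanly separable.
* **RMSF profiles** — wild type drawn around region-typical baselines
  (rigid TMs ≈ 0.7–0.9 Å/residue, mobile loops ≈ 1.5–1.8 Å/residue,
  scaled to the bundled wild-type reference sums, noise SD 0.05 Å);
  mutants are WT plus stated per-region shifts, so region sums and the
  cumulative statistic have arithmetic ground truth.
* **Energy frames** — i.i.d. normal components per entity with stated
  means/SDs (defaults sized like a protein–cofactor complex, ΔG ≈ −5
  kcal/mol); the closed-form ΔG mean and per-frame SD come with the
  sample. No force-field correlation structure — run-to-run
  autocorrelation of real MD is absent, so SE-based checks here are
  optimistic relative to real trajectories.

## Numerical choices and degenerate inputs

Strict inequalities follow the published wording: conservation mask
EC > 0.9, allele-frequency gate af > 1e-5, carrier floor > 50. Zero
carrier records make sex fractions undefined (explicit error). Frequency
columns distinguish missing (error) from zero (data), because the
non-pathogenic criterion depends on true ESP zeros. Ranking ties in
`top_frequent()` break by position then alternate residue. Timestamp
matching in `select_frames()` rounds to 1e-6 ps to dodge binary-fraction
noise. rSASA is clipped at 1.0 so sampling noise above the free-residue
reference cannot leave the valid range.

## Known limitations

The SASA engine is O(atoms² · points) pure R — fine for the coarse
models here, slow for large all-atom structures. The coarse SASA_max
table varies little across non-glycine types (CA + CB only); supply a
published table for all-atom work. The bundled reference region-RMSF
table ships printed values rounded to 0.1 Å, so recomputed cumulative
values can differ from printed ones by up to 0.2 Å (asserted at that
tolerance; 8 of 11 rows are exact). The discriminant thresholds were
calibrated on ten mutants of one protein and should not be ported to
other systems without re-deriving them.
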