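---
title: "Joint-condition ALE: model, decisions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-condition ALE: model, decisions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model implemented by `jointALE`,
the choices made where the method leaves room, and exactly what the
simulation-based validation does and does not establish.

## The problem

Voxel-based morphometry (VBM) studies report grey-matter differences
between a patient group and controls as peak stereotactic coordinates
(foci). Coordinate-based meta-analysis asks where such foci cluster across
studies more than chance. When two diagnostic conditions are suspected to
share a structural phenotype, analysing each condition separately and
overlaying thresholded maps conflates thresholding artefacts with true
overlap. The joint approach implemented here enters both conditions into
one analysis and quantifies, for every significant cluster, how much each
condition contributed to it.

## Model

**Kernel.** Every focus is modelled as an isotropic trivariate Gaussian
with FWHM 8 mm (σ = FWHM/(2√(2 ln 2)) ≈ 3.40 mm). The probability that a
focus hits voxel *v* is the density at the focus–voxel distance times the
voxel volume. We place mass by density × volume rather than integrating the
density over each voxel cube; at 2–4 mm voxels the difference is far below
grid error. The kernel is truncated at 4σ (≈ 13.6 mm), losing < 1e-4 of its
mass while making per-focus updates local.

**Study maps.** A study's likelihood map is the union of its per-focus hit
probabilities, `1 − Π(1 − p_i)` — the probability that at least one focus
of the study falls at the voxel. The union (rather than a voxelwise max or
plain additive smoothing) is the combination rule of the open-source ALE
lineage this implementation follows. Internally the product is accumulated
as `Σ log1p(−p)` and inverted with `expm1`, which is exact to machine
precision and verified voxel-for-voxel against a brute-force triple loop
in the tests.

**Condition means and the joint map.** Study maps are averaged within each
condition; the means are summed. Averaging first is what keeps the
condition that reported more foci (or more studies) from dominating the
joint map: each condition enters with unit weight regardless of corpus
size. Joint values live in [0, 2].

**Inference.** The null hypothesis is the absence of spatial association
between studies. Each of `n_permutations` permutations relocates every
focus to an independent uniform-random in-mask voxel center, preserving
per-study and per-condition focus counts, and recomputes the full
study → mean → joint pipeline. All in-mask joint values of all permutations
are pooled into a single null distribution; each observed voxel gets the
add-one p-value `(1 + #{null ≥ observed}) / (1 + N)`, which cannot be zero
and is a valid permutation p-value. The p-map is thresholded by
Benjamini–Hochberg FDR over in-mask voxels. Pooling across voxels (rather
than voxelwise nulls) matches the same ALE lineage and keeps 10,000
permutations tractable in memory; the pooled null is stored as a
fixed-width histogram of 32,768 bins on [0, 2] (bin width ≈ 6e-5), with
values in the observed value's own bin counted as ≥ observed — a
conservative tie rule whose effect is far below the permutation noise.

**Clusters.** Suprathreshold voxels are grouped by 26-connectivity
(configurable to 6 or 18); components are retained only if strictly larger
than 100 mm³. A study *supports* a cluster if any of its foci lies within
the kernel truncation radius of any cluster voxel — the farthest distance
at which the study's kernel mass can have contributed — and clusters
supported by fewer than two distinct studies are not reported. Clusters
carry both the peak-joint-value voxel and the intensity-weighted center of
mass.

**Contribution.** The attribution statistic integrates each condition's
mean map over the cluster:
`pct_A = 100 · Σ_c Ā / Σ_c (Ā + B̄)`. The two percentages sum to 100
exactly, are invariant to common rescaling of the maps, and swap exactly
under label exchange. Integration over the cluster (rather than reading
the ratio at the peak voxel) is the default because it is stable for small
clusters and reproduces the two interpretive anchors — a single-condition
cluster scores (100, 0), equal mean intensity scores (50, 50); the
peak-voxel variant is available via `contribution_method = "peak"`. The
A-only/B-only/shared classification (both percentages ≥ 20% → shared) is a
presentation convention for colour-coding maps, not part of the statistic.

**Directions.** Grey-matter deficits and excesses are analysed in two
fully independent runs; nothing is shared between them but the
configuration.

## Coordinate normalization

The working space is Talairach. Three input dialects are recognized:

* `TAL_NATIVE` — already Talairach; passed through.
* `MNI` — transformed with the Lancaster `icbm2tal` affine. Two published
  variants exist; the package pins the SPM-oriented matrix
  (`icbm_spm2tal`) as the default, since SPM-normalised VBM data are the
  dominant use case, and exposes the FSL variant
  (`lancaster_variant = "fsl"`).
* `TAL_BRETT` — Talairach coordinates that were originally produced with
  Brett's `mni2tal`. These are restored to MNI with the exact Brett
  inverse, then passed through `icbm2tal`, so all foci end on the same
  Lancaster-defined frame.

Brett's transform is piecewise linear with branches for z ≥ 0 and z < 0
selected on the *MNI* z. The inverse tries the z ≥ 0 inverse matrix and
accepts it iff the candidate MNI z is nonnegative. Because the two branch
matrices share their x and y columns, the candidate z is a positive
multiple of the true MNI z (the y-terms cancel algebraically), so this
branch rule reconstructs the original branch exactly and round trips are
exact to machine precision — there is no ambiguity band.

Coordinates beyond 120 mm in any axis are rejected as input errors; this
catches mm/voxel confusion without touching any real brain coordinate.

## Grid and mask

The method itself never states a grid, so the package defaults to 2 mm
isotropic voxels over x ∈ [−70, 70], y ∈ [−104, 68], z ∈ [−50, 78] mm —
the common ALE working box — with a diagonal affine (exact index/mm round
trips). Analyses of real corpora should supply a binary brain mask as
NIfTI (`read_mask()` resamples it to the grid by nearest neighbour);
when no mask is given, a procedurally generated smooth ellipsoid
(semi-axes 66 × 86 × 62 mm about (0, −18, 12)) stands in, keeping every
simulation and test self-contained. The ellipsoid is a deliberate
idealization: it has the right volume scale but no ventricles, sulci or
tissue classes.

## The synthetic-data generator

Real joint-ALE corpora are coordinate tables harvested from publications;
none are redistributable here, so validation runs on generated corpora
with known ground truth. The generator emulates the shape of a
two-condition VBM corpus: by default 15 studies for condition A and 10
for condition B (25 studies), per-study uniform background ("noise") foci
drawn 4–10 per study, and a set of ground-truth effect centers — two
shared, three A-only, two B-only, at plausible grey-matter Talairach
locations — each reported by a study with probability 0.9 and displaced by
isotropic Gaussian jitter of SD 6 mm. Six mm is of kernel order: clearly
above the voxel size (so discretization does not hide it) and below twice
the FWHM (so clusters can form at all). The defaults yield roughly 250–400
foci split about 60/40 between the conditions, mirroring the scale of
published joint corpora. Every emitted focus is attributed in a manifest
to exactly one center or to noise.

A center's strength has two axes: the fraction of studies reporting it and
the number of foci each reporting study contributes (`n_foci`). The second
models the common practice of reporting several subpeaks within one
robustly affected region. With a single focus per study and 6 mm jitter,
the asymptotic (many-study) height of a single-condition center in the
joint map is the jitter-smoothed kernel at the center, ≈ 0.012 per 64 mm³
voxel — at the edge of what survives FDR at realistic permutation counts;
such centers are detected only through finite-sample fluctuation. The
recovery validation therefore uses `n_foci = 2` centers ("strong signal"),
whose asymptotic height is twice that and which are recovered reliably.

What the generator does **not** emulate: anatomical structure (foci are
not confined to grey matter), publication bias and the file-drawer
problem, between-study differences in smoothing/thresholding, correlated
multi-peak reporting beyond the simple `n_foci` multiplicity, and
non-uniform background reporting density. Passing recovery tests on this
generator therefore demonstrates the *estimator's* correctness under its
own assumptions — not robustness to those real-data features.

## Validation design and problem sizes

The package's validation (tests and `scripts/acceptance.R`) uses scaled
problem sizes chosen to make each check statistically meaningful while
keeping a full run in minutes on one CPU:

* exactness checks (study map vs brute-force union; transform round
  trips) on ≤ 24³ grids and 1,000 random points, at 1e-12/1e-9
  tolerances;
* null calibration: 20 generated global-null corpora (no effect centers,
  noise 8–16 foci per study so totals match a real corpus), 4 mm grid,
  500 permutations each; the mean fraction of in-mask voxels with
  uncorrected p < 0.05 must lie in 0.05 ± 0.01;
* false-positive control: the same 20 runs must yield zero retained
  clusters after FDR, volume and support filters in ≥ 95% of runs;
* contribution recovery: 20 corpora with an A-only and a 50/50 strong
  center (12 studies per condition, `n_foci = 2`, noise 2–6), 4 mm grid,
  1,000 permutations; the A-only cluster must be recovered in every seed
  with mean contribution ≥ 95% (individual seeds can dip when a
  background focus of the other condition happens to fall within kernel
  reach of the cluster — the statistic is then correctly reporting real
  cross-condition mass), and the shared cluster's mean contribution must
  lie in 50 ± 10;
* determinism: identically seeded runs must produce byte-identical
  cluster tables.

The publication-scale protocol (2 mm grid, 10,000 permutations) is the
package default and is what a real analysis should run; the validation
sizes above are a deliberate trade of grid resolution for replicate count.

## Known limitations

* The permutation scheme (uniform relocation, pooled null) is the
  canonical reconstruction of the ALE lineage's null; original
  implementations vary in details that are rarely documented.
* The contribution statistic is descriptive; no inferential test on the
  percentages is provided (none is defined by the method).
* No atlas labelling: clusters are reported as coordinates, not
  anatomical names.
* Sample-size-weighted kernels and anisotropic kernels (later ALE
  refinements) are out of scope.
* The built-in ellipsoid mask is for self-contained simulation; real
  analyses should pass a proper brain mask.
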