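---
title: "Quantifying between-subject variability of EEG electrode positions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying between-subject variability of EEG electrode positions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electrovar)
```

## The problem

EEG electrodes are placed on the scalp at proportional distances between
skull landmarks (the 10-10 system), and analyses routinely assume that a
given electrode overlies approximately the same cortical territory in
every participant. When electrode positions can be localized per subject
on a structural MR image — for instance from the conductive-gel
artifacts each electrode leaves on a T1 scan — that assumption becomes
measurable: mark each electrode on each subject's reconstructed scalp,
project it to the cortical surface, map everything into a common (MNI)
space, and ask how much the position of each electrode varies across
people and which brain regions actually lie underneath it.

`electrovar` implements that measurement pipeline as composable stages:

1. **coordinate I/O** — plain-text per-subject target tables
   (`label, x, y, z` in mm) and 4x4 subject-to-MNI affine matrices, as
   produced by neuro-navigation exports and SPM-style affine
   normalization;
2. **spatial normalization** — exact application of each subject's own
   affine (`normalize_cohort()`); no resampling, no nonlinear warp,
   because the consumed matrix is the affine component only;
3. **cortical projection** — a deterministic replacement for proprietary
   "snap to" tools: peel the brain mask by a chosen depth, then take the
   nearest point on the peeled surface (`peel_surface()`,
   `snap_to_cortex()`);
4. **variability statistics** — per-electrode cross-subject mean, SD,
   skewness, overall deviation; grand SDs; extreme-electrode rankings;
   cap-size subgroup summaries;
5. **atlas labeling** — highest-probability region per electrode and
   subject with tie/no-label exclusions, percentage tallies over usable
   subjects, and nearest-label (Brodmann-style) lookup at cohort mean
   coordinates;
6. **volume rendering** — NIfTI point maps and SD-coded sphere maps for
   overlay on an MNI template;
7. **synthetic cohorts** — a generative stand-in for MRI-derived data
   with known ground truth, so every stage above is testable end to end.

## The statistics

For electrode $e$ with positions $p_{se} \in \mathbb{R}^3$ across the
$n_e$ subjects contributing it (subjects missing the electrode are
excluded, not imputed), the package reports per axis $a$:

* mean $\bar p_{ea}$ and sample SD $s_{ea}$ (always the $n-1$
  denominator);
* skewness, by default the plain Fisher–Pearson coefficient
  $g_1 = m_3 / m_2^{3/2}$ on central moments with $1/n$ weights; the
  bias-adjusted $G_1 = g_1\sqrt{n(n-1)}/(n-2)$ is available via
  `adjusted_skewness = TRUE`. The choice matters little at $n = 20$
  (the adjustment is a factor 1.084) and published tables rarely state
  the estimator; we default to the simpler one and expose the other.
* the *overall deviation* $(s_{ex} + s_{ey} + s_{ez})/3$, used to rank
  electrodes from most stable to most variable.

The *grand SD* per axis is the unweighted mean over electrodes of the
per-electrode SDs — a "mean standard deviation", not a pooled SD over
all subject-by-electrode deviations. The two differ when electrode
counts differ, and the mean-of-SDs form is what published cap
variability tables report. Cap-size subgroup summaries recompute the
per-electrode SDs inside each subgroup before averaging; subjects with
an unrecorded cap size appear only in the `All` row, and singleton
groups are reported with missing SDs rather than zeros.

With one observation, SD and skewness are `NA`, never 0; a zero-variance
sample has skewness 0 by convention (it is symmetric about its mean).

## Atlas labeling rules

`query_prob_atlas()` maps an MNI coordinate to a voxel with
nearest-voxel rounding through the atlas's inverse affine — the behavior
of single-coordinate atlas query tools — rather than interpolating
probabilities. `max_label()` then applies three mutually exclusive
outcomes: the unique maximum-probability region (`REGION`); a tie at the
maximum (`TIE`, the subject is excluded for that electrode); or no
label at all (`NONE`, likewise excluded; this happens outside the atlas
or at background voxels). Percentages in `tally_regions()` are taken
over the *usable* count (the `REGION` outcomes only), so they always sum
to 100 when any subject is usable. Ties are detected by exact equality
at the atlas's stored precision — synthetic atlases store integer
probabilities for exactly this reason, since ties are only meaningful at
the precision an atlas actually encodes.

The nearest-label lookup (`nearest_label()`) operates on the cohort
*mean* coordinate per electrode, returns the containing voxel's label if
there is one, otherwise the nearest labeled voxel center within a 10 mm
radius (distance ties go to the smaller label integer), and reports no
label beyond that radius — the expected outcome for inferior electrodes
whose mean position overlies cerebellum in a cortex-only parcellation.
Hemisphere is reported mechanically from the sign of mean x (negative =
left), with |x| < 2 mm flagged `"midline"` instead, because a signed
left/right call is not meaningful within measurement noise of the
midsagittal plane.

## The projection model

Commercial "snap to" projection is unpublished, so the package defines a
reproducible equivalent: the brain mask is metrically eroded by
`peel_depth_mm` (a spherical structuring element on voxel-center
distances), the eroded mask's outer boundary voxels (those with a
background face-neighbor) form the surface cloud, and each scalp point
moves to the Euclidean-nearest cloud point, with exact distance ties
broken by smallest x, then y, then z. `slice_spacing_mm` and
`end_depth_mm` are accepted so that parameter sets from curvilinear
reconstructions can be carried through verbatim, but they do not change
the geometry here: what those parameters do to the snapped point inside
the proprietary implementation is not documented, and we prefer an inert
parameter to a guessed one. Electrodes farther than `max_search_mm`
(default 50 mm) from the surface are flagged unprojectable and dropped
from downstream statistics.

Representing the surface as boundary-voxel centers rather than a mesh
bounds the projection error by about half a voxel diagonal; at the 1-4
mm grids used here that is well below the 4-7 mm positional effects
being measured. The projection is idempotent (a snapped point snaps to
itself), and radial placement noise is compressed by the projection
since the surface pins the radial coordinate — mirroring the empirical
observation that cortex-projected grand SDs fall below scalp grand SDs.

## The synthetic cohort generator

The generator emulates the statistical structure of a fixed-cap cohort,
not its anatomy. A subject's head is a pair of nested ellipsoids (scalp
and brain); the 65-label 10-10 montage is constructed from angular
proportions on the sphere (midline arc in 10% steps, circumferential
ring at 72 degrees inclination in 18-degree steps, inner rows by
spherical interpolation, and FT9/FT10/TP9/TP10 one step below the ring
so they project inferiorly) and seated on the scalp by radial
projection. Per-subject noise has two levels:

* a **cap-level** perturbation — small rigid rotation (SD 2 degrees per
  Euler axis), translation (SD 3 mm per axis) and isotropic scale (SD
  2%) of the whole cap, re-seated on the scalp, producing the spatially
  correlated component of placement error;
* an **electrode-level** iid Gaussian jitter (SD 3 mm per axis by
  default), producing the independent component (gel-artifact marking
  error, local cap stretch).

These defaults land per-axis grand SDs in the 4-7 mm range reported for
MRI-localized fixed-cap cohorts; they are a plausible operating point,
not a fit — no published decomposition of cap-level versus
electrode-level variance exists to calibrate against. Cap sizes default
to 54/56/58 cm split 4/12/3 with one unrecorded subject in a cohort of
20, scaling both ellipsoids by `cap_cm / 56`; this exercises the grouped
statistics including the missing-category path. Each subject is finally
expressed in a randomized native space (rotation, translation, scale),
and the generator returns the exact inverse as that subject's
subject-to-MNI affine — so normalization is exercised nontrivially and
has an exact round-trip oracle.

Random streams are keyed by (seed, subject, electrode): electrode
missingness (2% by default) removes rows without shifting any other
electrode's draws, and identical seeds give bit-identical cohorts.

What the generator does *not* emulate: cortical folding (the "cortex" is
a smooth ellipsoid), MR intensity data and gel-artifact appearance,
digitization operator bias, and any anatomically realistic covariance
between neighboring electrodes beyond the shared cap transform. Tests
passing on synthetic cohorts therefore validate the *pipeline
arithmetic* — transforms, projections, estimators, exclusion rules —
not claims about real anatomy.

## Numerical choices

* Affines are validated on construction: homogeneous last row to 1e-9,
  upper 3x3 determinant above 1e-12; application is the exact linear
  map; inversion round-trips random points below 1e-9 mm.
* World-to-voxel lookups round to the nearest voxel; voxel indices are
  0-based against NIfTI-convention affines throughout.
* The single geometry predicate "voxel center within radius" is shared
  by the ellipsoid voxelizer and the sphere renderer, so brute-force
  lattice enumeration is a common oracle for both.
* Sphere overlaps in rendered maps resolve to the maximum intensity
  (the larger SD wins visually); the maps are for visualization, so any
  consistent rule is acceptable and this one never hides a hotspot.
* Text round-trips (targets, affines, CSVs) write at 17 significant
  digits and are exact to 1e-9 or better; readers reject truncated rows
  rather than padding them.
* `rank_extremes()` breaks deviation ties alphabetically in both the
  smallest and largest sets, making rankings deterministic.

## Problem sizes used in the checks

The bundled checks run on deliberately small instances chosen to keep
the full suite fast while leaving no code path untested: cohorts of
4-20 subjects; mask grids of 31-70 voxels per side at 1-4 mm; a
200-replicate recovery study (20 subjects, 5 mm jitter) whose mean
grand SD must land within 2% of the closed-form expectation
c4(20) x 5 mm = 4.935 mm; and a 1000-point exhaustive nearest-neighbor
comparison for the projection. The acceptance script
(`scripts/acceptance.R`) re-runs these same computations from scratch at
a caller-chosen seed.

## Known limitations

* Only the affine component of spatial normalization is supported; if a
  study's coordinates were produced with a nonlinear warp, the matrices
  consumed here cannot reproduce them.
* The projection operates on binary masks; partial-volume or meshed
  surfaces are out of scope, and projection error grows with voxel
  size.
* Real probabilistic atlases (Harvard-Oxford and friends) are consumed
  from user-supplied NIfTI files but not shipped; all bundled atlas
  volumes are synthetic and labelled as such.
* Which surface (scalp or cortex) should feed atlas labeling is a study
  design choice, not something the package infers; `label_surface`
  makes it explicit and defaults to cortex.
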