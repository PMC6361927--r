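---
title: "Methods: Vim localization geometry, phantoms and multi-atlas fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Vim localization geometry, phantoms and multi-atlas fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and numerical choices
behind `vimloc`, in the spirit of a methods section: what each component
assumes, which parameters matter, and what the synthetic phantoms do and do
not establish about real data.

## Coordinate frame and volumes

All geometry lives in a world-millimetre AC-PC frame: the anterior
commissure at the origin, `x+` toward the subject's right, `y+` anterior,
`z+` superior. Grids are axis-aligned with positive spacings; the world
position of (1-based) voxel `(i, j, k)` is `origin + (i-1, j-1, k-1) *
spacing`, and **every geometric operation works on voxel centers**. NIfTI
files with rotated or sheared affines are rejected rather than resampled:
inter-subject and inter-contrast registration is deliberately out of scope
(phantom cohorts share one grid, emulating already-registered data), so
supporting oblique grids would only add silent error sources. The default
spacing, 0.4 mm isotropic, matches the resolution the targeting workflow
uses clinically; 0.5 mm grids are equally supported by constructing the
`VoxelGrid` explicitly.

One numerical convention applies package-wide: quantities compared against
a geometric boundary (the ellipsoid inequality during voxelization, the
normalized subregion coordinates) are snapped to nine decimals first. Voxel
centers that lie *exactly* on a sphere surface or a cuboid diagonal are
common at these spacings (e.g. a 2 mm radius is exactly five 0.4 mm
voxels), and without snapping their inclusion flips with ulp-level rounding
noise, breaking exact mirror symmetry and lattice-translation invariance.
Nine decimals is far below any anatomical scale and far above double
rounding error, so the snap only stabilizes ties.

## The Guiot construction

`constructGuiotTarget()` builds the indirect target from the landmark set
(AC, PC, thalamus height, third-ventricle lateral wall). The laterality —
wall plus 11 mm — is the classical, fixed part of the construction. The
remaining coordinates are *not* fully standardized across the literature,
so they are exposed in `GuiotParams` as package defaults rather than
presented as canonical: the target sits at a fraction 0.25 of the PC-to-AC
distance anterior of PC, and on the AC-PC plane (`zOffsetMm = 0`). Both are
plausible mid-range choices for the anterio-inferior Vim; users comparing
against a local clinical protocol should set their own values.

Blind re-targeting is simulated by perturbing every landmark coordinate
independently and uniformly within `±jitterMm` (default 0.2 mm — half a
voxel) and quantizing the reconstructed target to the nearest voxel center.
The uniform-plus-quantization model is a deliberate simplification: the
construction is linear in the landmarks, so each target coordinate inherits
a jitter bounded by the landmark jitter, and with half-voxel jitter the
quantized repetitions can differ by at most about one voxel — which is the
qualitative behaviour reported for repeated manual constructions.
Reproducibility is summarized by Euclidean distances between quantized
points with the first repetition as the reference, matching how repeated
targeting is audited clinically.

## The eight-subregion decomposition

`subdivideROI()` computes the smallest axis-aligned cuboid over the ROI's
voxel centers, then assigns every ROI voxel a label in
{superior, inferior} × {anterior, lateral, posterior, ventral}. Superior vs
inferior is decided by the cuboid's axial mid-plane. The in-plane quadrant
uses coordinates normalized by the cuboid half-extents — `u` positive
toward the lateral side of the stated hemisphere, `v` positive anterior —
so the dividing lines are the *diagonals of the axial rectangle* (they join
its corners), not 45-degree lines in millimetres; for elongated structures
these differ substantially, and the corner-diagonal reading is the one
consistent with a rectangle-based construction. "Ventral" names the
medial-facing quadrant, keeping the terminology used for this subdivision
in the tremor-targeting literature even though geometrically it is the
medial triangle.

Ties are deterministic and documented: a voxel exactly on the mid-plane is
superior; after excluding strict anterior (`v > |u|`) and strict posterior
(`v < -|u|`), `u >= 0` goes to lateral and `u < 0` to ventral, which also
places the exact center in the lateral quadrant. A consequence worth
knowing: for a symmetric cube the lateral and ventral quadrants are
slightly larger than anterior/posterior, because diagonal-tie voxels are
assigned rather than split. A flat ROI (zero x or y extent) has no axial
rectangle and is rejected as degenerate. `classifyPoint()` applies the same
rule to a single point and additionally flags points within a tolerance
(default 0.05 in normalized units) of the mid-plane or a diagonal as "on
the boundary" — used only for reporting, never for the partition.

## Spatial relations

"Adjacent to a border" is operationalized metrically: boundary voxels are
mask voxels with at least one 6-connected face neighbour outside the mask
(grid edges count as outside), and a subregion border is reported as
adjacent when the minimum distance between the inner ROI's boundary voxel
centers and that subregion's share of the outer boundary is at most
`thresholdMm` (default 1 mm, i.e. 2-3 voxels). The threshold is a package
decision — visual "next to" judgments have no published quantitative
counterpart — and the report is monotone in it, so sensitivity analyses are
one loop. Centroids are unweighted means of voxel centers (binary masks
carry no intensity weighting), and a centroid beyond the reference cuboid
is reported as `"outside"` rather than raising an error, since that is a
legitimate finding for disjoint structures.

## Overlap metrics and the cohort table

Dice is `2|A∩B| / (|A|+|B|)` in voxel counts, errors on two empty masks,
and all cohort standard deviations are sample (n-1) standard deviations.
Normalized volumes are percentages of the whole-thalamus volume, which is
what makes Vim and VLV sizes comparable across hemispheres and subjects.
The packaged `table1.csv` transcribes the study cohort's volumetry exactly
as printed (missing cells are empty, never zero: one subject's left Vim was
obscured by a vessel, excluding that subject from the multi-atlas columns).
The mean VLV/Vim size ratio is computed from the normalized-percent columns
over the rows that carry a manual delineation; with the table's rounded
entries, raw-volume and per-case-ratio routes give values between 14 and
16, and the normalized-percent route is the one documented in the function
contract.

## The synthetic anatomy

The phantom generator's job is to produce ground truth with the right
*statistical structure*, not photorealism. Structures are ellipsoids: an
ovoid thalamus per hemisphere (default 7.6 cm³, mirrored about the
midplane), a VLV sub-ellipsoid clipped to the thalamus, and a small Vim
ellipsoid clipped to the VLV. Ellipsoids are the simplest shape family with
controllable volume, extents and relative position, which is all the
downstream geometry consumes.

Defaults encode the anatomy the pipeline targets: VLV at 15% of the
thalamic volume, Vim at 1.0%, and Vim extents in the 3 × 8 × 5 mm
(AP × DV × ML) mid-range of the classical electrophysiological dimensions.
Because clipping removes part of the nominal ellipsoid, both the VLV and
the Vim are *rescaled by bisection until their realized, voxel-counted,
clipped volumes hit the per-subject targets*, so target fractions are met
by construction rather than approximately. The Vim's lateral position is
not free: at every bisection step its center is recomputed so the lateral
tip overshoots the analytic VLV surface by 0.3 mm, which after clipping
pins the Vim against the lateral VLV border (surface distance 0) in the
inferior, weakly anterior part of the cluster — the configuration the
comparison analyses are designed to detect. With the default 25 mm AC-PC
distance and 2 mm ventricle wall, the default Guiot construction lands
inside this Vim's ventral part, so the phantom reproduces the qualitative
clinical geometry end to end.

The SWI-like intensity volume renders the Vim hyperintense (160) between
darker Vc (posterior) and Vo (superior-anterior) regions (70), generic
thalamus/VLV tissue at 110, background at 50, a pulvinar with a
lateral-dark to medial-bright gradient, additive Gaussian noise (sd 5), and
optional dark vessel cylinders of random orientation. The Vim-to-surround
contrast of ~10 noise standard deviations is deliberately comfortable: the
phantoms test the *machinery* (standardization, fusion, geometry), not the
hard perceptual problem of low-contrast elderly data, and no claim about
real-data segmentation accuracy follows from phantom Dice values.

Cohort variability uses per-subject jitter drawn from uniform ranges:
whole-complex translation ±0.8 mm, per-structure translation ±0.4 mm
(the Vim's lateral coordinate stays pinned), thalamic volume ±10%, Vim
fraction ±20% relative, VLV fraction ±10% relative. The translation scale
emulates residual misalignment of the order a constrained non-rigid
registration leaves behind (~1 mm), and the fraction ranges keep realized
values inside the anatomically reported 0.4-1.5% (Vim) and 13-19% (VLV)
bands. What the phantom does *not* emulate: true shape variability beyond
affine-like perturbations, partial-volume effects, bias fields, or
susceptibility physics.

All randomness flows through one explicitly seeded generator per call;
cohort subjects get seeds derived deterministically from the master seed,
so cohorts are bitwise reproducible.

## Intensity standardization and label fusion

Standardization follows the decile-landmark approach: per-VOI percentile
landmarks (p1, p10, ..., p90, p99; p1/p99 as robust extrema — plain minima
and maxima would let single vessel voxels stretch the scale) are computed
within the thalamus mask, averaged over the training cohort, and mapped
affinely onto a standard range of [0, 100]. A target VOI is standardized by
the piecewise-linear map sending its own landmarks onto the scale's, with
linear extrapolation beyond p1/p99 from the terminal segments. The map is
monotone and exactly cancels global affine intensity transforms of the
input. Fewer than 100 masked voxels, or constant intensities, are rejected
(the percentiles would be meaningless). Within the leave-one-out harness
the scale is built from the training atlases of the current fold — keeping
every fold free of target information — rather than from a fixed
subcohort.

Label fusion offers three estimators of the per-voxel Vim probability.
Majority voting is the unweighted mean. Locally weighted voting uses
`w_i(v) ∝ exp(-beta * MSD_i(v))` with MSD the mean squared difference
between target and atlas patches (cubic, radius 2 voxels, zero-padded at
VOI edges); the per-voxel minimum MSD is subtracted before exponentiation,
which is an exact renormalization that avoids underflow at `beta = 1` on
the [0, 100] intensity scale. Joint weighting solves
`w(v) = (M + eps I)^-1 1`, normalized to unit sum, where `M_ij(v)` is the
patchwise mean product of atlases i's and j's absolute intensity errors
against the target — so atlases that make *correlated* errors share one
vote instead of outvoting an independent atlas. `M` is a Gram matrix of
nonnegative vectors, hence positive semidefinite, and the ridge
`eps = 1e-6` guarantees solvability; joint weights can legitimately be
negative, so the fused probability is clipped to [0, 1]. At voxels where
all atlases agree the fused probability equals the consensus label for any
weights summing to one, so weights are only solved where atlases disagree —
an exact optimization, not an approximation. The final mask thresholds the
probability at 0.5. The corrective-learning post-processing step that
sometimes accompanies joint fusion is a trained component and is
intentionally not part of this package.

## Problem sizes and what the tests establish

The test suite and the acceptance script run the pipeline at the study's
natural scales, chosen as the package's reference experiment sizes: 100
random masks for the geometric oracle comparison, 500 six-repetition
targeting sessions, 20 phantom subjects (40 hemispheres) for
volume-fraction recovery, and an 8-subject phantom cohort (16 leave-one-out
folds, 7 atlases each) for fusion. On the default 96³ grid a subject
generates in about a second and the full leave-one-out experiment takes a
few tens of seconds.

Green phantom tests establish that the geometry, standardization and
fusion code do what their contracts say under controlled truth. They do
not establish real-data segmentation accuracy: real 7T SWI adds
registration error, vessels crossing the target, and age-dependent
contrast loss, and the reported phantom Dice values (typically ~0.8) sit
well above what manual-delineation agreement reaches on real data.
Reproducing real-data numbers would require the original images and
registrations, which is outside this package's scope.

## Known limitations

* Ellipsoid anatomy cannot represent concave nuclei or touching-but-
  distinct structures; adjacency conclusions transfer only qualitatively.
* The Guiot anterior-posterior fraction and plane height are package
  defaults, not a clinical standard; results depending on them should be
  reported with the parameter values.
* `minSurfaceDistance()` is exact but O(|boundary A| x |boundary B|);
  it is intended for thalamus-scale structures, not whole-brain masks.
* Only axis-aligned grids are supported by design; data on oblique grids
  must be resampled upstream.
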