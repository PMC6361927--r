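# vimloc

Analysis tools for localizing the **ventro-intermediate thalamic nucleus
(Vim)** — the stereotactic target for drug-resistant tremor — relative to
the indirect clinical targeting construction and to automated segmentation,
with a synthetic thalamic-anatomy phantom generator that supplies ground
truth for every stage.

The Vim cannot be seen on routine MRI, so clinical targeting is indirect:
the *quadrilatere of Guiot* places a single point from stereotactic
landmarks (AC, PC, thalamus height, third-ventricle lateral wall), at 11 mm
lateral of the third-ventricle wall. Modern alternatives delineate
structure instead of a point: a diffusion-based parcellation yields the
motor (VLV) cluster that encloses the Vim, and multi-atlas segmentation of
SWI contrast can outline the Vim itself. This package implements the
geometry and statistics needed to compare all three against a reference
delineation, for an audience of neuroimaging methods researchers.

## What it computes

* **Guiot targeting** (`constructGuiotTarget`, `simulateRepeatedTargeting`,
  `targetingReproducibility`): the landmark construction, a blind
  re-targeting simulator with uniform landmark jitter and voxel
  quantization, and Euclidean distance-to-first reproducibility.
* **ROI geometry** (`boundingCuboid`, `subdivideROI`, `classifyPoint`): the
  smallest bounding cuboid of a region and its partition into eight
  subregions — the cuboid mid-plane separates superior/inferior, the axial
  rectangle's diagonals separate the anterior, lateral, posterior and
  ventral (medial) quadrants.
* **Spatial relations** (`containmentFraction`, `minSurfaceDistance`,
  `adjacencyReport`, `centroidLocalization`,
  `cohortLocalizationSummary`): containment of one region in another,
  boundary-to-boundary distance, which subregion borders a region touches,
  and centroid classification.
* **Overlap metrics** (`volumeMm3`, `normalizedVolumePct`,
  `diceCoefficient` = 2|A∩B|/(|A|+|B|), `vlvVimRatioSummary`,
  `cohortReport`): volumes, thalamus-normalized percentages, Dice, and
  cohort summaries. A transcription of the study cohort's volumetry ships
  as `inst/extdata/table1.csv`.
* **Multi-atlas segmentation** (`extractVOI`, `buildStandardScale`,
  `standardizeIntensities`, `fuseLabels`, `looExperiment`): thalamic VOI
  extraction, Nyul-style decile-landmark intensity standardization, label
  fusion by majority vote, locally weighted voting
  (w ∝ exp(−β·MSD)), or joint weighting w ∝ (M+εI)⁻¹1 with M the matrix of
  patchwise products of absolute intensity errors, and a leave-one-out
  cross-validation harness.
* **Synthetic anatomy** (`PhantomSpec`, `generateSubject`,
  `generateCohort`, `structureMask`): phantom subjects with a thalamus,
  a VLV cluster (~15% of the thalamus), a Vim (~1%) pinned against the
  inferior lateral VLV border, SWI-like hyperintense-Vim contrast with
  darker Vc/Vo neighbours, optional vessel artifacts, and per-subject
  jitter for cohort experiments.

Volumes are NIfTI-1 (`readVolume` / `writeVolume`, axis-aligned AC-PC
frame, via RNifti); landmark sets are JSON; tables are CSV.

## Worked example

```r
library(vimloc)

subj <- generateSubject(PhantomSpec(), seed = 7)
subj
#> SyntheticSubject
#>   left  thalamus 6947 mm^3; VLV 15.9%; Vim 62.4 mm^3 (0.90%)
#>   right thalamus 6853 mm^3; VLV 14.5%; Vim 81.9 mm^3 (1.19%)

vim <- structureMask(subj, "vim", "right")
vlv <- structureMask(subj, "vlv", "right")
containmentFraction(vim, vlv)        # 1: the VLV encloses the Vim
adjacencyReport(vim, vlv, "right")   # includes "inferior-lateral"

gt <- constructGuiotTarget(subj@landmarks, hemisphere = "right")
gt@point
#> [1]  13.00 -18.75   0.00
centroidLocalization(sphereROI(gt@point, 2, voxelGrid(vim)), vim, "right")
#> $subregion: "inferior-ventral"   $on_boundary: FALSE
```

The Guiot point lands 13 mm lateral (2 mm ventricle wall + 11 mm offset),
a quarter of the AC–PC distance anterior of PC, on the AC–PC plane — and
its 2 mm sphere sits in the ventral part of the phantom Vim. A
leave-one-out fusion experiment on a phantom cohort:

```r
cohort <- generateCohort(PhantomSpec(), 8, seed = 7)
loo <- looExperiment(cohort)
round(c(mean = loo$mean_dice, sd = loo$sd_dice), 3)
#>  mean    sd
#> 0.814 0.093
```

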