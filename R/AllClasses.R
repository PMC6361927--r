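#' @import methods
NULL

# ---------------------------------------------------------------------------
# Coordinate frame: world millimetres in AC-PC space, anterior commissure at
# the origin by default; x+ = subject right (lateral on the right side),
# y+ = anterior, z+ = superior. Grids are axis-aligned (no rotation); the
# world coordinate of 1-based voxel (i,j,k) is origin + (i-1, j-1, k-1) *
# spacing, i.e. all geometry operates on voxel centers.
# ---------------------------------------------------------------------------

#' VoxelGrid: an axis-aligned 3D sampling grid
#'
#' Defines the geometry shared by all volumes in the package: the number of
#' voxels per axis, the isotropic or anisotropic spacing in millimetres, and
#' the world coordinate (mm, AC-PC frame) of the center of the first voxel.
#'
#' @slot shape integer vector of length 3, voxels per axis (nx, ny, nz).
#' @slot spacing numeric vector of length 3, mm per voxel along each axis.
#' @slot origin numeric vector of length 3, world mm of voxel (1,1,1) center.
#' @export
setClass("VoxelGrid",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be 3 integers >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelGrid
#'
#' @param shape integer triple (nx, ny, nz).
#' @param spacing mm per axis; a scalar is recycled (isotropic grid).
#' @param origin world mm of the first voxel center. The default centers the
#'   grid on the origin (AC).
#' @return A [VoxelGrid-class] object.
#' @examples
#' VoxelGrid(c(96, 96, 96), 0.4)
#' @export
VoxelGrid <- function(shape, spacing = 0.4, origin = NULL) {
  shape <- as.integer(shape)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(origin))
    origin <- -(shape - 1L) * spacing / 2
  new("VoxelGrid", shape = shape, spacing = spacing,
      origin = as.numeric(origin))
}

# Virtual parent for all gridded data
setClass("Volume", representation(grid = "VoxelGrid", data = "array",
                                  "VIRTUAL"))

setValidity("Volume", function(object) {
  if (!identical(dim(object@data), as.integer(object@grid@shape)))
    "data dimensions must equal grid shape" else TRUE
})

#' ROIMask: a binary region-of-interest volume
#'
#' Voxel values are 0 (background) or 1 (inside the region).
#'
#' @slot grid a [VoxelGrid-class].
#' @slot data integer array of 0/1 matching the grid shape.
#' @export
setClass("ROIMask", contains = "Volume")

setValidity("ROIMask", function(object) {
  v <- unique(as.vector(object@data))
  if (!all(v %in% c(0L, 1L))) "mask values must be 0 or 1" else TRUE
})

#' Construct an ROIMask
#'
#' @param data logical or 0/1 numeric array.
#' @param grid a [VoxelGrid-class] matching `dim(data)`.
#' @export
ROIMask <- function(data, grid) {
  d <- array(as.integer(data != 0), dim = dim(data))
  new("ROIMask", grid = grid, data = d)
}

#' LabelVolume: an integer-labelled volume
#'
#' @slot grid a [VoxelGrid-class].
#' @slot data integer array; 0 is background.
#' @slot labelMap named integer vector mapping structure names to label codes.
#' @export
setClass("LabelVolume", contains = "Volume",
         representation(labelMap = "integer"))

setValidity("LabelVolume", function(object) {
  msg <- character()
  if (is.null(names(object@labelMap)) ||
      any(!nzchar(names(object@labelMap))))
    msg <- c(msg, "labelMap must be a named integer vector")
  present <- setdiff(unique(as.vector(object@data)), 0L)
  if (!all(present %in% object@labelMap))
    msg <- c(msg, "every nonzero label value must appear in labelMap")
  if (length(msg)) msg else TRUE
})

#' Construct a LabelVolume
#'
#' @param data integer array (0 = background).
#' @param grid a [VoxelGrid-class].
#' @param labelMap named integer vector (name -> label code).
#' @export
LabelVolume <- function(data, grid, labelMap) {
  new("LabelVolume", grid = grid,
      data = array(as.integer(data), dim = dim(data)),
      labelMap = structure(as.integer(labelMap), names = names(labelMap)))
}

#' IntensityVolume: a scalar-valued volume
#'
#' @slot grid a [VoxelGrid-class].
#' @slot data numeric array matching the grid shape.
#' @export
setClass("IntensityVolume", contains = "Volume")

#' @rdname IntensityVolume-class
#' @param data numeric array.
#' @param grid a [VoxelGrid-class].
#' @export
IntensityVolume <- function(data, grid) {
  new("IntensityVolume", grid = grid,
      data = array(as.numeric(data), dim = dim(data)))
}

#' LandmarkSet: stereotactic landmarks for indirect targeting
#'
#' The landmarks used by the quadrilatere-of-Guiot construction: the anterior
#' and posterior commissures, the superior thalamic border height, and the
#' lateral wall of the third ventricle per hemisphere.
#'
#' @slot ac,pc world mm points (AC must be anterior to PC: `ac[2] > pc[2]`).
#' @slot thalamusHeightMm z of the superior thalamic border, mm.
#' @slot wallXMm named numeric `c(left=, right=)`, |x| of the third-ventricle
#'   lateral wall per hemisphere (>= 0).
#' @slot hemisphere `"left"`, `"right"` or `"both"`.
#' @export
setClass("LandmarkSet",
  representation(ac = "numeric", pc = "numeric",
                 thalamusHeightMm = "numeric", wallXMm = "numeric",
                 hemisphere = "character"))

setValidity("LandmarkSet", function(object) {
  msg <- character()
  if (length(object@ac) != 3L || length(object@pc) != 3L)
    msg <- c(msg, "ac and pc must be world mm triples")
  else if (!(object@ac[2] > object@pc[2]))
    msg <- c(msg, "AC must lie anterior to PC (ac[2] > pc[2])")
  if (!(length(object@thalamusHeightMm) == 1L &&
        object@thalamusHeightMm > 0))
    msg <- c(msg, "thalamusHeightMm must be a single positive number")
  if (!all(c("left", "right") %in% names(object@wallXMm)) ||
      any(object@wallXMm < 0))
    msg <- c(msg, "wallXMm must be named c(left=, right=) with values >= 0")
  if (!object@hemisphere %in% c("left", "right", "both"))
    msg <- c(msg, "hemisphere must be 'left', 'right' or 'both'")
  if (length(msg)) msg else TRUE
})

#' Construct a LandmarkSet
#'
#' @param ac,pc AC and PC world mm points.
#' @param thalamusHeightMm superior thalamic border z, mm.
#' @param wallXMm lateral third-ventricle wall |x| per hemisphere; a scalar is
#'   used for both sides.
#' @param hemisphere which side(s) the set describes.
#' @export
LandmarkSet <- function(ac, pc, thalamusHeightMm, wallXMm,
                        hemisphere = "both") {
  if (is.null(names(wallXMm)))
    wallXMm <- c(left = unname(wallXMm[1]),
                 right = unname(wallXMm[length(wallXMm)]))
  new("LandmarkSet", ac = as.numeric(ac), pc = as.numeric(pc),
      thalamusHeightMm = as.numeric(thalamusHeightMm),
      wallXMm = wallXMm[c("left", "right")], hemisphere = hemisphere)
}

#' GuiotParams: parameters of the quadrilatere-of-Guiot construction
#'
#' Only the 11 mm laterality from the third-ventricle wall is fixed by the
#' classical construction; the anterior-posterior fraction and the height
#' relative to the AC-PC plane are package defaults kept configurable.
#'
#' @slot lateralOffsetMm laterality from the third-ventricle wall (default 11).
#' @slot apFraction fraction of the PC->AC distance, measured anterior from
#'   PC (default 0.25).
#' @slot zOffsetMm height relative to the AC-PC plane (default 0).
#' @slot sphereRadiusMm radius of the target sphere emulating the 90 Gy
#'   isodose line (default 2).
#' @export
setClass("GuiotParams",
  representation(lateralOffsetMm = "numeric", apFraction = "numeric",
                 zOffsetMm = "numeric", sphereRadiusMm = "numeric"))

setValidity("GuiotParams", function(object) {
  msg <- character()
  if (object@lateralOffsetMm <= 0) msg <- c(msg, "lateralOffsetMm must be > 0")
  if (object@apFraction <= 0 || object@apFraction >= 1)
    msg <- c(msg, "apFraction must lie in (0, 1)")
  if (object@sphereRadiusMm <= 0) msg <- c(msg, "sphereRadiusMm must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname GuiotParams-class
#' @param lateralOffsetMm,apFraction,zOffsetMm,sphereRadiusMm see slots.
#' @export
GuiotParams <- function(lateralOffsetMm = 11, apFraction = 0.25,
                        zOffsetMm = 0, sphereRadiusMm = 2) {
  new("GuiotParams", lateralOffsetMm = lateralOffsetMm,
      apFraction = apFraction, zOffsetMm = zOffsetMm,
      sphereRadiusMm = sphereRadiusMm)
}

#' GuiotTarget: a constructed stereotactic target point
#'
#' @slot point world mm target.
#' @slot quantizedPoint nearest voxel center on the session grid (NA if no
#'   grid was supplied).
#' @slot hemisphere `"left"` or `"right"`.
#' @slot params the [GuiotParams-class] used.
#' @slot landmarks the [LandmarkSet-class] used.
#' @export
setClass("GuiotTarget",
  representation(point = "numeric", quantizedPoint = "numeric",
                 hemisphere = "character", params = "GuiotParams",
                 landmarks = "LandmarkSet"))

#' TargetingSession: repeated Guiot constructions for reproducibility analysis
#'
#' @slot targets list of [GuiotTarget-class] (first target = reference).
#' @slot grid the quantization [VoxelGrid-class].
#' @slot jitterMm per-coordinate landmark perturbation half-range, mm.
#' @slot seed integer seed used.
#' @export
setClass("TargetingSession",
  representation(targets = "list", grid = "VoxelGrid", jitterMm = "numeric",
                 seed = "integer"))

setValidity("TargetingSession", function(object) {
  if (length(object@targets) < 2L)
    "a session needs at least 2 targets for reproducibility analysis"
  else TRUE
})

#' BoundingCuboid: the smallest axis-aligned cuboid containing an ROI
#'
#' Bounds are over the world coordinates of included voxel centers.
#'
#' @slot min,max per-axis world mm bounds.
#' @slot center,extents cuboid center and edge lengths, mm.
#' @slot hemisphere `"left"` or `"right"`; decides which x direction counts
#'   as lateral.
#' @export
setClass("BoundingCuboid",
  representation(min = "numeric", max = "numeric", center = "numeric",
                 extents = "numeric", hemisphere = "character"))

setValidity("BoundingCuboid", function(object) {
  msg <- character()
  if (any(object@min > object@max)) msg <- c(msg, "min must be <= max")
  if (!object@hemisphere %in% c("left", "right"))
    msg <- c(msg, "hemisphere must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' SubregionMap: the eight-subregion decomposition of an ROI
#'
#' Each ROI voxel carries one of eight labels: \{superior, inferior\} crossed
#' with \{anterior, lateral, posterior, ventral\}.
#'
#' @slot labels a [LabelVolume-class] with codes 1..8 over the ROI.
#' @slot cuboid the [BoundingCuboid-class] the decomposition is based on.
#' @slot boundaryToleranceMm tolerance (normalized units) used when reporting
#'   points as lying "around" a dividing plane.
#' @export
setClass("SubregionMap",
  representation(labels = "LabelVolume", cuboid = "BoundingCuboid",
                 boundaryTolerance = "numeric"))

#' PhantomSpec: configuration of the synthetic thalamic-anatomy generator
#'
#' Defaults emulate the anatomy the pipeline is designed for: a ~7.6 cm^3
#' thalamus per hemisphere, a motor (VLV) cluster occupying ~15% of it, and a
#' Vim occupying ~1% placed in the inferior anterior-lateral VLV against its
#' lateral border, appearing hyperintense between darker Vc/Vo regions on the
#' SWI-like intensity volume.
#'
#' @slot grid sampling grid (default 96^3 voxels at 0.4 mm).
#' @slot thalamusVolumeMm3 target thalamic volume per hemisphere (default 7600).
#' @slot vlvFraction VLV volume as a fraction of the thalamus (default 0.15).
#' @slot vimFraction Vim volume as a fraction of the thalamus (default 0.010).
#' @slot vimExtentMm full Vim extents, mm, in anterio-posterior/dorso-ventral/
#'   medio-lateral order (default 3/8/5); the shape is scaled uniformly to hit
#'   `vimFraction`.
#' @slot vimPlacement normalized offsets (lateral, anterior, superior) of the
#'   Vim center inside the VLV, as fractions of the VLV semi-axes; the lateral
#'   component is recomputed so the Vim touches the lateral VLV border.
#' @slot swiParams named numeric: mean intensities for background, thalamus,
#'   vlv, vim, vc, vo, pulvinarMedial, pulvinarLateral, vessel, and noiseSd.
#' @slot vesselParams list(count, radiusMm, enabled).
#' @slot subjectJitter list of perturbation half-ranges used for cohort
#'   generation: translationMm (whole complex), structureTranslationMm,
#'   volumeRel (thalamus), vimFractionRel, vlvFractionRel.
#' @export
setClass("PhantomSpec",
  representation(grid = "VoxelGrid", thalamusVolumeMm3 = "numeric",
                 vlvFraction = "numeric", vimFraction = "numeric",
                 vimExtentMm = "numeric", vimPlacement = "numeric",
                 swiParams = "numeric", vesselParams = "list",
                 subjectJitter = "list"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!(object@vimFraction > 0 && object@vimFraction < object@vlvFraction &&
        object@vlvFraction < 1))
    msg <- c(msg, "need 0 < vimFraction < vlvFraction < 1")
  if (any(object@vimExtentMm <= 0))
    msg <- c(msg, "vimExtentMm must be positive")
  if (object@thalamusVolumeMm3 <= 0)
    msg <- c(msg, "thalamusVolumeMm3 must be positive")
  need <- c("background", "thalamus", "vlv", "vim", "vc", "vo",
            "pulvinarMedial", "pulvinarLateral", "vessel", "noiseSd")
  if (!all(need %in% names(object@swiParams)))
    msg <- c(msg, paste("swiParams must contain:",
                        paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @rdname PhantomSpec-class
#' @param grid,thalamusVolumeMm3,vlvFraction,vimFraction,vimExtentMm see slots.
#' @param vimPlacement,swiParams,vesselParams,subjectJitter see slots.
#' @export
PhantomSpec <- function(grid = VoxelGrid(c(96L, 96L, 96L), 0.4,
                                         origin = c(-19.2, -34, -12)),
                        thalamusVolumeMm3 = 7600,
                        vlvFraction = 0.15,
                        vimFraction = 0.010,
                        vimExtentMm = c(ap = 3, dv = 8, ml = 5),
                        vimPlacement = c(lateral = 0.45, anterior = 0.05,
                                         superior = -0.35),
                        swiParams = c(background = 50, thalamus = 110,
                                      vlv = 110, vim = 160, vc = 70, vo = 70,
                                      pulvinarMedial = 120,
                                      pulvinarLateral = 70, vessel = 30,
                                      noiseSd = 5),
                        vesselParams = list(count = 2L, radiusMm = 0.4,
                                            enabled = TRUE),
                        subjectJitter = list(translationMm = 0.8,
                                             structureTranslationMm = 0.4,
                                             volumeRel = 0.10,
                                             vimFractionRel = 0.20,
                                             vlvFractionRel = 0.10)) {
  new("PhantomSpec", grid = grid, thalamusVolumeMm3 = thalamusVolumeMm3,
      vlvFraction = vlvFraction, vimFraction = vimFraction,
      vimExtentMm = as.numeric(vimExtentMm),
      vimPlacement = as.numeric(vimPlacement), swiParams = swiParams,
      vesselParams = vesselParams, subjectJitter = subjectJitter)
}

#' SyntheticSubject: one generated phantom subject
#'
#' @slot labels a [LabelVolume-class]; each voxel carries its finest
#'   structure label (use [structureMask()] to recover nested masks:
#'   Vim inside VLV inside thalamus).
#' @slot intensity the SWI-like [IntensityVolume-class].
#' @slot landmarks the subject's [LandmarkSet-class] (both hemispheres).
#' @slot spec the [PhantomSpec-class] used.
#' @slot truth list of realized per-hemisphere volumes and fractions, the
#'   per-subject jitter draws, and the vessel mask.
#' @export
setClass("SyntheticSubject",
  representation(labels = "LabelVolume", intensity = "IntensityVolume",
                 landmarks = "LandmarkSet", spec = "PhantomSpec",
                 truth = "list"))

#' StandardScale: decile landmarks of the intensity standardization
#'
#' Percentile landmarks (robust extrema p1/p99 plus the deciles) averaged over
#' a training cohort and affinely mapped onto a fixed standard range.
#'
#' @slot percentiles the percentile levels, in percent.
#' @slot landmarks the standard-scale landmark intensities (non-decreasing).
#' @slot sMin,sMax ends of the standard range.
#' @export
setClass("StandardScale",
  representation(percentiles = "numeric", landmarks = "numeric",
                 sMin = "numeric", sMax = "numeric"))

setValidity("StandardScale", function(object) {
  msg <- character()
  if (is.unsorted(object@landmarks))
    msg <- c(msg, "landmarks must be non-decreasing")
  if (!(object@sMin < object@sMax)) msg <- c(msg, "need sMin < sMax")
  if (length(object@percentiles) != length(object@landmarks))
    msg <- c(msg, "percentiles and landmarks must have equal length")
  if (length(msg)) msg else TRUE
})

#' FusionParams: parameters of multi-atlas label fusion
#'
#' @slot method `"majority"`, `"local_weighted"` or `"joint"`.
#' @slot patchRadius cubic patch radius in voxels (default 2).
#' @slot beta sharpness of the local similarity weights (default 1).
#' @slot epsilon ridge added to the joint dependency matrix (default 1e-6).
#' @slot threshold decision threshold on the fused probability (default 0.5).
#' @export
setClass("FusionParams",
  representation(method = "character", patchRadius = "integer",
                 beta = "numeric", epsilon = "numeric",
                 threshold = "numeric"))

setValidity("FusionParams", function(object) {
  msg <- character()
  if (!object@method %in% c("majority", "local_weighted", "joint"))
    msg <- c(msg, "method must be majority, local_weighted or joint")
  if (object@patchRadius < 0L) msg <- c(msg, "patchRadius must be >= 0")
  if (object@beta <= 0) msg <- c(msg, "beta must be > 0")
  if (object@epsilon <= 0) msg <- c(msg, "epsilon must be > 0")
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname FusionParams-class
#' @param method,patchRadius,beta,epsilon,threshold see slots.
#' @export
FusionParams <- function(method = "joint", patchRadius = 2L, beta = 1,
                         epsilon = 1e-6, threshold = 0.5) {
  new("FusionParams", method = method, patchRadius = as.integer(patchRadius),
      beta = beta, epsilon = epsilon, threshold = threshold)
}

#' AtlasCase: one atlas (intensity + label) for multi-atlas fusion
#'
#' @slot subjectId identifier.
#' @slot intensity standardized intensity VOI ([IntensityVolume-class]).
#' @slot label the structure label VOI ([ROIMask-class]) on the same grid.
#' @slot hemisphere `"left"` or `"right"`.
#' @export
setClass("AtlasCase",
  representation(subjectId = "character", intensity = "IntensityVolume",
                 label = "ROIMask", hemisphere = "character"))

setValidity("AtlasCase", function(object) {
  if (!isTRUE(all.equal(object@intensity@grid@origin,
                        object@label@grid@origin)) ||
      !identical(object@intensity@grid@shape, object@label@grid@shape))
    "intensity and label must share one grid" else TRUE
})

#' @rdname AtlasCase-class
#' @param subjectId,intensity,label,hemisphere see slots.
#' @export
AtlasCase <- function(subjectId, intensity, label, hemisphere) {
  new("AtlasCase", subjectId = as.character(subjectId),
      intensity = intensity, label = label, hemisphere = hemisphere)
}

#' CohortTable: per-subject, per-hemisphere volumetry
#'
#' One row per (subject, hemisphere): manual and multi-atlas Vim volumes
#' (mm^3) with their thalamus-normalized percentages, and the motor-cluster
#' (VLV) volume (cm^3) with its normalized percentage. Missing cells (cases
#' where a delineation was impossible) are NA.
#'
#' @slot data a data.frame with columns subject_id, hemisphere,
#'   vim_manual_mm3, vim_manual_pct, vim_multiatlas_mm3, vim_multiatlas_pct,
#'   vlv_cm3, vlv_pct.
#' @export
setClass("CohortTable", representation(data = "data.frame"))

cohortColumns <- c("subject_id", "hemisphere", "vim_manual_mm3",
                   "vim_manual_pct", "vim_multiatlas_mm3",
                   "vim_multiatlas_pct", "vlv_cm3", "vlv_pct")

setValidity("CohortTable", function(object) {
  d <- object@data
  msg <- character()
  if (!all(cohortColumns %in% names(d)))
    return(paste("missing columns:",
                 paste(setdiff(cohortColumns, names(d)), collapse = ", ")))
  if (nrow(d)) {
    if (!all(d$hemisphere %in% c("left", "right")))
      msg <- c(msg, "hemisphere must be 'left' or 'right'")
    if (anyDuplicated(d[c("subject_id", "hemisphere")]))
      msg <- c(msg, "at most one row per (subject, hemisphere)")
    vols <- unlist(d[c("vim_manual_mm3", "vim_multiatlas_mm3", "vlv_cm3")])
    if (any(vols < 0, na.rm = TRUE))
      msg <- c(msg, "volumes must be >= 0")
    pcts <- unlist(d[c("vim_manual_pct", "vim_multiatlas_pct", "vlv_pct")])
    if (any(pcts < 0 | pcts > 100, na.rm = TRUE))
      msg <- c(msg, "percentages must lie in [0, 100]")
  }
  if (length(msg)) msg else TRUE
})

#' OverlapReport: Dice and volumes for a pair of masks
#'
#' @slot dice Dice coefficient 2|A^B|/(|A|+|B|).
#' @slot volAMm3,volBMm3,intersectionMm3 volumes in mm^3.
#' @export
setClass("OverlapReport",
  representation(dice = "numeric", volAMm3 = "numeric", volBMm3 = "numeric",
                 intersectionMm3 = "numeric"))

#' SpatialRelationRecord: spatial relations of an inner ROI within an outer ROI
#'
#' @slot subjectId,hemisphere identifiers.
#' @slot containmentFraction |inner ^ outer| / |inner|.
#' @slot minSurfaceDistanceMm minimum boundary-to-boundary distance.
#' @slot centroidSubregion subregion of the outer bounding cuboid containing
#'   the inner centroid ("outside" if beyond the cuboid).
#' @slot centroidOnBoundary logical; whether the centroid lies around a
#'   dividing plane (NA when outside).
#' @slot adjacentTo outer subregions whose border the inner ROI approaches
#'   within the adjacency threshold.
#' @export
setClass("SpatialRelationRecord",
  representation(subjectId = "character", hemisphere = "character",
                 containmentFraction = "numeric",
                 minSurfaceDistanceMm = "numeric",
                 centroidSubregion = "character",
                 centroidOnBoundary = "logical", adjacentTo = "character"))
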