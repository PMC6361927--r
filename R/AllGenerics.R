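# Accessor generics and show methods.

#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))
#' Accessors for gridded volumes
#'
#' `voxelGrid()` returns the [VoxelGrid-class]; `arrayData()` the raw array;
#' `gridSpacing()`, `gridOrigin()` and `gridShape()` the grid geometry;
#' `voxelCount()` the number of nonzero voxels; `labelMap()` the name-to-code
#' map of a [LabelVolume-class].
#'
#' @param x a volume or grid object.
#' @return See description.
#' @rdname accessors
#' @aliases voxelGrid
setMethod("voxelGrid", "Volume", function(x) x@grid)

#' @export
setGeneric("arrayData", function(x) standardGeneric("arrayData"))
#' @rdname accessors
#' @aliases arrayData
setMethod("arrayData", "Volume", function(x) x@data)

#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @aliases gridSpacing
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)
setMethod("gridSpacing", "Volume", function(x) x@grid@spacing)

#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @aliases gridOrigin
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)
setMethod("gridOrigin", "Volume", function(x) x@grid@origin)

#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname accessors
#' @aliases gridShape
setMethod("gridShape", "VoxelGrid", function(x) x@shape)
setMethod("gridShape", "Volume", function(x) x@grid@shape)

#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))
#' @rdname accessors
#' @aliases voxelCount
setMethod("voxelCount", "ROIMask", function(x) sum(x@data))

#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname accessors
#' @aliases labelMap
setMethod("labelMap", "LabelVolume", function(x) x@labelMap)

#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))
#' Extract the data.frame of a CohortTable
#' @param x a [CohortTable-class].
#' @return The underlying data.frame.
#' @rdname cohortData
#' @aliases cohortData
setMethod("cohortData", "CohortTable", function(x) x@data)

#' @export
setMethod("as.data.frame", "CohortTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@data)

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(object@shape, collapse = "x"),
              paste(format(object@spacing), collapse = ", "),
              paste(format(object@origin), collapse = ", ")))
})

setMethod("show", "ROIMask", function(object) {
  cat(sprintf("ROIMask: %d voxels set (%.2f mm^3)\n", sum(object@data),
              sum(object@data) * prod(object@grid@spacing)))
  show(object@grid)
})

setMethod("show", "LabelVolume", function(object) {
  cat("LabelVolume with labels:\n")
  cnt <- tabulate(object@data, nbins = max(object@labelMap))
  for (nm in names(object@labelMap)) {
    code <- object@labelMap[[nm]]
    cat(sprintf("  %2d %-16s %d voxels\n", code, nm,
                if (code <= length(cnt)) cnt[code] else 0L))
  }
  show(object@grid)
})

setMethod("show", "IntensityVolume", function(object) {
  cat(sprintf("IntensityVolume: range [%.3g, %.3g]\n",
              min(object@data), max(object@data)))
  show(object@grid)
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf(paste0("LandmarkSet (%s): AC (%s), PC (%s), thalamus height ",
                     "%.1f mm, wall |x| L %.1f / R %.1f mm\n"),
              object@hemisphere,
              paste(format(object@ac), collapse = ", "),
              paste(format(object@pc), collapse = ", "),
              object@thalamusHeightMm, object@wallXMm[["left"]],
              object@wallXMm[["right"]]))
})

setMethod("show", "GuiotTarget", function(object) {
  cat(sprintf("GuiotTarget (%s): (%s) mm", object@hemisphere,
              paste(format(object@point), collapse = ", ")))
  if (!anyNA(object@quantizedPoint))
    cat(sprintf("; quantized (%s) mm",
                paste(format(object@quantizedPoint), collapse = ", ")))
  cat("\n")
})

setMethod("show", "TargetingSession", function(object) {
  cat(sprintf("TargetingSession: %d repetitions, jitter %.2f mm, seed %d\n",
              length(object@targets), object@jitterMm, object@seed))
})

setMethod("show", "BoundingCuboid", function(object) {
  cat(sprintf("BoundingCuboid (%s): extents (%s) mm, center (%s) mm\n",
              object@hemisphere,
              paste(format(object@extents), collapse = ", "),
              paste(format(object@center), collapse = ", ")))
})

setMethod("show", "SubregionMap", function(object) {
  cat("SubregionMap:\n")
  cnt <- tabulate(object@labels@data, nbins = 8L)
  nms <- names(sort(object@labels@labelMap))
  for (i in seq_len(8L))
    cat(sprintf("  %-18s %d voxels\n", nms[i], cnt[i]))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: thalamus %.0f mm^3, VLV %.1f%%, ",
                     "Vim %.2f%% of thalamus\n"),
              object@thalamusVolumeMm3, 100 * object@vlvFraction,
              100 * object@vimFraction))
  show(object@grid)
})

setMethod("show", "SyntheticSubject", function(object) {
  cat("SyntheticSubject\n")
  for (h in c("left", "right")) {
    tr <- object@truth[[h]]
    cat(sprintf(paste0("  %-5s thalamus %.0f mm^3; VLV %.1f%%; Vim %.1f ",
                       "mm^3 (%.2f%%)\n"), h,
                tr$thalamus_mm3, tr$vlv_pct, tr$vim_mm3, tr$vim_pct))
  }
})

setMethod("show", "StandardScale", function(object) {
  cat(sprintf("StandardScale on [%g, %g]: %s\n", object@sMin, object@sMax,
              paste(sprintf("p%g=%.1f", object@percentiles,
                            object@landmarks), collapse = " ")))
})

setMethod("show", "CohortTable", function(object) {
  cat(sprintf("CohortTable: %d rows\n", nrow(object@data)))
  if (nrow(object@data)) print(utils::head(object@data, 18L))
})

setMethod("show", "OverlapReport", function(object) {
  cat(sprintf(paste0("OverlapReport: Dice %.3f; |A| %.1f mm^3, |B| %.1f ",
                     "mm^3, |A^B| %.1f mm^3\n"), object@dice,
              object@volAMm3, object@volBMm3, object@intersectionMm3))
})

setMethod("show", "SpatialRelationRecord", function(object) {
  cat(sprintf(paste0("SpatialRelationRecord %s/%s: containment %.3f, min ",
                     "surface distance %.2f mm,\n  centroid in %s%s, ",
                     "adjacent to {%s}\n"),
              object@subjectId, object@hemisphere,
              object@containmentFraction, object@minSurfaceDistanceMm,
              object@centroidSubregion,
              ifelse(isTRUE(object@centroidOnBoundary),
                     " (around a plane)", ""),
              paste(object@adjacentTo, collapse = ", ")))
})
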