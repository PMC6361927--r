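# Spatial relations between regions: containment, surface distance,
# adjacency to specific borders of the eight-subregion decomposition, and
# centroid localization.

#' Containment fraction of one ROI within another
#'
#' Fraction of the inner mask's voxels that lie inside the outer mask,
#' `|inner ^ outer| / |inner|`.
#'
#' @param inner,outer [ROIMask-class] objects on the same grid; `inner`
#'   must be nonempty.
#' @return A number in `[0, 1]`.
#' @export
containmentFraction <- function(inner, outer) {
  stopIfGridMismatch(inner, outer)
  n <- voxelCount(inner)
  if (n == 0L) stop("inner mask is empty", call. = FALSE)
  sum(inner@data & outer@data) / n
}

#' Minimum surface distance between two ROIs
#'
#' Boundary voxels are mask voxels with at least one 6-connected face
#' neighbour outside the mask (the grid edge counts as outside). The
#' distance is the minimum Euclidean distance between boundary voxel
#' centers of the two masks; 0 when the boundaries share a voxel.
#'
#' @param a,b nonempty [ROIMask-class] objects on the same grid.
#' @return Distance in mm.
#' @export
minSurfaceDistance <- function(a, b) {
  stopIfGridMismatch(a, b)
  if (voxelCount(a) == 0L || voxelCount(b) == 0L)
    stop("both masks must be nonempty", call. = FALSE)
  ba <- boundaryArray(a@data)
  bb <- boundaryArray(b@data)
  if (any(ba & bb)) return(0)
  minPairwiseDistance(maskCoords(a@grid, ba), maskCoords(b@grid, bb))
}

#' Which outer subregion borders is an inner ROI adjacent to?
#'
#' Subdivides the outer ROI into its eight geometric subregions and reports
#' every subregion whose share of the outer boundary lies within
#' `thresholdMm` of the inner ROI's boundary. The report is monotone
#' non-decreasing in the threshold.
#'
#' @param inner a nonempty [ROIMask-class].
#' @param outer a nonempty [ROIMask-class] on the same grid.
#' @param hemisphere `"left"` or `"right"` (lateral direction of the
#'   subdivision).
#' @param thresholdMm adjacency threshold (default 1 mm, i.e. 2-3 voxels at
#'   the default resolutions).
#' @return Character vector of subregion labels.
#' @export
adjacencyReport <- function(inner, outer, hemisphere = c("right", "left"),
                            thresholdMm = 1.0) {
  hemisphere <- match.arg(hemisphere)
  stopIfGridMismatch(inner, outer)
  if (voxelCount(inner) == 0L) stop("inner mask is empty", call. = FALSE)
  submap <- subdivideROI(outer, hemisphere)
  outerBoundary <- boundaryArray(outer@data)
  innerB <- maskCoords(inner@grid, boundaryArray(inner@data))
  out <- character()
  for (lab in subregionNames()) {
    border <- outerBoundary & (submap@labels@data == subregionCodes()[lab])
    if (!any(border)) next
    d <- minPairwiseDistance(innerB, maskCoords(outer@grid, border))
    if (d <= thresholdMm) out <- c(out, lab)
  }
  out
}

#' Localize the centroid of a mask within a reference ROI
#'
#' The centroid is the unweighted mean of the mask's voxel centers; it is
#' classified against the reference ROI's bounding cuboid with the
#' eight-subregion rule. A centroid beyond the cuboid is reported as
#' `"outside"` rather than an error.
#'
#' @param mask,reference nonempty [ROIMask-class] objects on the same grid.
#' @param hemisphere `"left"` or `"right"`.
#' @param boundaryTolerance tolerance passed to [classifyPoint()].
#' @return `list(subregion, on_boundary)`.
#' @export
centroidLocalization <- function(mask, reference,
                                 hemisphere = c("right", "left"),
                                 boundaryTolerance = 0.05) {
  hemisphere <- match.arg(hemisphere)
  stopIfGridMismatch(mask, reference)
  if (voxelCount(mask) == 0L || voxelCount(reference) == 0L)
    stop("both masks must be nonempty", call. = FALSE)
  centroid <- colMeans(maskCoords(mask@grid, mask@data))
  cuboid <- boundingCuboid(reference, hemisphere)
  eps <- 1e-9
  if (any(centroid < cuboid@min - eps) || any(centroid > cuboid@max + eps))
    return(list(subregion = "outside", on_boundary = NA))
  classifyPoint(cuboid, centroid, boundaryTolerance)
}

#' Build a full spatial-relation record for an (inner, outer) pair
#'
#' Convenience wrapper computing containment, minimum surface distance, the
#' inner centroid's subregion of the outer cuboid, and the adjacency report
#' in one pass.
#'
#' @param inner,outer nonempty [ROIMask-class] objects on the same grid.
#' @param subjectId,hemisphere identifiers.
#' @param thresholdMm adjacency threshold in mm.
#' @return A [SpatialRelationRecord-class].
#' @export
spatialRelationRecord <- function(inner, outer, subjectId = "",
                                  hemisphere = c("right", "left"),
                                  thresholdMm = 1.0) {
  hemisphere <- match.arg(hemisphere)
  loc <- centroidLocalization(inner, outer, hemisphere)
  new("SpatialRelationRecord",
      subjectId = as.character(subjectId), hemisphere = hemisphere,
      containmentFraction = containmentFraction(inner, outer),
      minSurfaceDistanceMm = minSurfaceDistance(inner, outer),
      centroidSubregion = loc$subregion,
      centroidOnBoundary = as.logical(loc$on_boundary),
      adjacentTo = adjacencyReport(inner, outer, hemisphere, thresholdMm))
}

#' Cohort-level localization summary
#'
#' Counts the records satisfying a predicate and reports the fraction as a
#' percentage with one decimal (e.g. 16 of 17 -> 94.1).
#'
#' @param records list of [SpatialRelationRecord-class] objects.
#' @param predicate function taking a record and returning TRUE/FALSE.
#' @return `list(count, total, fraction_pct)`.
#' @examples
#' # fraction of cases whose Vim touches the inferior-lateral border:
#' # cohortLocalizationSummary(records,
#' #   function(r) "inferior-lateral" %in% r@adjacentTo)
#' @export
cohortLocalizationSummary <- function(records, predicate) {
  if (!length(records)) stop("no records supplied", call. = FALSE)
  hits <- vapply(records, function(r) isTRUE(predicate(r)), logical(1L))
  list(count = sum(hits), total = length(hits),
       fraction_pct = round(100 * sum(hits) / length(hits), 1L))
}
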