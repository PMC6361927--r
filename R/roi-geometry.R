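# Bounding cuboid and the eight-subregion geometric decomposition of an ROI.
#
# A mid-plane at the cuboid's half-height separates superior from inferior;
# the two diagonals of the cuboid's axial rectangle (normalized by the half
# extents, so they join the rectangle corners) separate the anterior,
# lateral, posterior and ventral (medial-facing) in-plane quadrants.

subregionNames <- function() {
  as.vector(outer(c("superior", "inferior"),
                  c("anterior", "lateral", "posterior", "ventral"),
                  paste, sep = "-"))
}

subregionCodes <- function() {
  structure(1:8, names = subregionNames())
}

#' Smallest bounding cuboid of an ROI
#'
#' Axis-aligned tight bounds over the world coordinates of the nonzero voxel
#' centers.
#'
#' @param mask a nonempty [ROIMask-class].
#' @param hemisphere `"left"` or `"right"`; decides which x direction is
#'   lateral in downstream subdivision.
#' @return A [BoundingCuboid-class].
#' @export
boundingCuboid <- function(mask, hemisphere = c("right", "left")) {
  hemisphere <- match.arg(hemisphere)
  if (voxelCount(mask) == 0L) stop("mask is empty", call. = FALSE)
  xyz <- maskCoords(mask@grid, mask@data)
  lo <- unname(apply(xyz, 2L, min))
  hi <- unname(apply(xyz, 2L, max))
  new("BoundingCuboid", min = lo, max = hi, center = (lo + hi) / 2,
      extents = hi - lo, hemisphere = hemisphere)
}

# Normalized in-plane coordinates: u is positive toward the lateral side of
# the given hemisphere, v positive anterior, both scaled by the half extents.
# Tie-breaks (documented contract): z == center -> superior; after excluding
# strict anterior (v > |u|) and strict posterior (v < -|u|), u >= 0 ->
# lateral (this covers u = v = 0), u < 0 -> ventral.
classifyUVZ <- function(u, v, zAbove) {
  quadrant <- ifelse(v > abs(u), "anterior",
              ifelse(v < -abs(u), "posterior",
              ifelse(u >= 0, "lateral", "ventral")))
  paste(ifelse(zAbove, "superior", "inferior"), quadrant, sep = "-")
}

normalizedCoords <- function(cuboid, xyz) {
  half <- cuboid@extents / 2
  if (half[1] <= 0 || half[2] <= 0)
    stop("degenerate cuboid: zero extent in x or y; the eight-subregion ",
         "rule needs a nonflat axial section (supply a thicker ROI)",
         call. = FALSE)
  s <- if (cuboid@hemisphere == "right") 1 else -1
  u <- s * (xyz[, 1] - cuboid@center[1]) / half[1]
  v <- (xyz[, 2] - cuboid@center[2]) / half[2]
  zp <- if (half[3] > 0) (xyz[, 3] - cuboid@center[3]) / half[3]
        else rep(0, nrow(xyz))
  # snap to 9 decimals so exact geometric ties (voxels on a diagonal or the
  # mid-plane) are classified identically regardless of rounding noise in
  # the world coordinates (e.g. for a mask and its x-mirror)
  round(cbind(u = u, v = v, z = zp), 9L)
}

#' Subdivide an ROI into eight geometric subregions
#'
#' Computes the smallest bounding cuboid of the ROI, separates superior from
#' inferior voxels at the cuboid mid-plane, and assigns each voxel an
#' in-plane quadrant (anterior, lateral, posterior, or ventral = medial)
#' using the diagonals of the cuboid's axial rectangle. Every ROI voxel gets
#' exactly one of the eight labels.
#'
#' @param mask a nonempty [ROIMask-class]; its axial section must have
#'   positive x and y extents.
#' @param hemisphere `"left"` or `"right"` (which x direction is lateral).
#' @param boundaryTolerance tolerance in normalized units used by
#'   [classifyPoint()] when flagging points as lying around a dividing plane
#'   (default 0.05). Not used for the partition itself.
#' @return A [SubregionMap-class].
#' @examples
#' g <- VoxelGrid(c(12, 12, 12), 0.4)
#' m <- ROIMask(array(1, c(12, 12, 12)), g)
#' table(arrayData(subdivideROI(m, "right")@labels))
#' @export
subdivideROI <- function(mask, hemisphere = c("right", "left"),
                         boundaryTolerance = 0.05) {
  hemisphere <- match.arg(hemisphere)
  cuboid <- boundingCuboid(mask, hemisphere)
  idx <- which(mask@data != 0)
  arr <- which(mask@data != 0, arr.ind = TRUE)
  xyz <- voxelToWorld(mask@grid, arr)
  uvz <- normalizedCoords(cuboid, xyz)
  labels <- classifyUVZ(uvz[, 1], uvz[, 2], uvz[, 3] >= 0)
  codes <- subregionCodes()
  data <- array(0L, dim = dim(mask@data))
  data[idx] <- codes[labels]
  new("SubregionMap",
      labels = LabelVolume(data, mask@grid, codes),
      cuboid = cuboid, boundaryTolerance = boundaryTolerance)
}

#' Classify a world point against a bounding cuboid
#'
#' Applies the same eight-subregion rule as [subdivideROI()] to a single
#' point, and additionally reports whether the point lies within
#' `boundaryTolerance` (normalized units) of the mid-plane or of one of the
#' in-plane diagonals.
#'
#' @param cuboid a [BoundingCuboid-class].
#' @param point world mm point; must lie inside the cuboid.
#' @param boundaryTolerance tolerance in normalized units (default 0.05).
#' @return `list(subregion = <label>, on_boundary = <logical>)`.
#' @export
classifyPoint <- function(cuboid, point, boundaryTolerance = 0.05) {
  point <- as.numeric(point)
  eps <- 1e-9
  if (any(point < cuboid@min - eps) || any(point > cuboid@max + eps))
    stop("point lies outside the cuboid", call. = FALSE)
  uvz <- normalizedCoords(cuboid, matrix(point, 1L))
  u <- uvz[1, 1]; v <- uvz[1, 2]; zp <- uvz[1, 3]
  onb <- abs(zp) <= boundaryTolerance ||
    min(abs(u - v), abs(u + v)) <= boundaryTolerance
  list(subregion = classifyUVZ(u, v, zp >= 0), on_boundary = onb)
}
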