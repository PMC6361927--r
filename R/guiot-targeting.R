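# Quadrilatere-of-Guiot targeting: landmark-based construction of the Vim
# target point, a repeated-targeting simulator, and reproducibility metrics.

acpcPlaneZ <- function(landmarks) (landmarks@ac[3] + landmarks@pc[3]) / 2

#' Construct the quadrilatere-of-Guiot target point
#'
#' The target sits at the configured laterality from the third-ventricle
#' lateral wall (default 11 mm), at a configurable fraction of the PC-to-AC
#' distance anterior from PC (default 0.25), at a configurable height
#' relative to the AC-PC plane (default on the plane). The construction is
#' fully deterministic and linear in the landmarks.
#'
#' @param landmarks a [LandmarkSet-class].
#' @param params a [GuiotParams-class].
#' @param hemisphere `"left"` or `"right"`; defaults to the landmark set's
#'   hemisphere. Requesting a side that contradicts a single-sided landmark
#'   set is an error.
#' @param grid optional [VoxelGrid-class]; if given, the target is also
#'   quantized to the nearest voxel center.
#' @return A [GuiotTarget-class].
#' @examples
#' lm <- LandmarkSet(ac = c(0, 12.5, 0), pc = c(0, -12.5, 0),
#'                   thalamusHeightMm = 16, wallXMm = 2)
#' constructGuiotTarget(lm, hemisphere = "right")@point  # c(13, -6.25, 0)
#' @export
constructGuiotTarget <- function(landmarks, params = GuiotParams(),
                                 hemisphere = NULL, grid = NULL) {
  if (is.null(hemisphere)) {
    if (landmarks@hemisphere == "both")
      stop("landmarks cover both hemispheres; say which side to target",
           call. = FALSE)
    hemisphere <- landmarks@hemisphere
  }
  if (!hemisphere %in% c("left", "right"))
    stop("hemisphere must be 'left' or 'right'", call. = FALSE)
  if (landmarks@hemisphere != "both" && landmarks@hemisphere != hemisphere)
    stop("landmark set is for the ", landmarks@hemisphere,
         " hemisphere but the ", hemisphere, " target was requested",
         call. = FALSE)
  s <- if (hemisphere == "right") 1 else -1
  point <- c(
    s * (landmarks@wallXMm[[hemisphere]] + params@lateralOffsetMm),
    landmarks@pc[2] + params@apFraction * (landmarks@ac[2] - landmarks@pc[2]),
    acpcPlaneZ(landmarks) + params@zOffsetMm)
  q <- if (is.null(grid)) rep(NA_real_, 3L) else snapToGrid(grid, point)
  new("GuiotTarget", point = point, quantizedPoint = q,
      hemisphere = hemisphere, params = params, landmarks = landmarks)
}

#' Simulate repeated, independent Guiot targeting
#'
#' Emulates blind re-targeting: each repetition perturbs every landmark
#' coordinate (AC, PC, and the third-ventricle wall) independently and
#' uniformly within `+-jitterMm`, reconstructs the target, and quantizes it
#' to the nearest voxel center of `grid`.
#'
#' @param landmarks a [LandmarkSet-class].
#' @param params a [GuiotParams-class].
#' @param grid quantization [VoxelGrid-class].
#' @param nRep number of repetitions (>= 2; default 6).
#' @param jitterMm per-coordinate uniform half-range in mm (default 0.2,
#'   half a voxel at 0.4 mm).
#' @param seed integer seed; the session is deterministic given the seed.
#' @param hemisphere side to target (defaults to the landmark set's side).
#' @return A [TargetingSession-class].
#' @seealso [targetingReproducibility()]
#' @export
simulateRepeatedTargeting <- function(landmarks, params = GuiotParams(),
                                      grid, nRep = 6L, jitterMm = 0.2,
                                      seed = 1L, hemisphere = NULL) {
  if (nRep < 2L) stop("nRep must be >= 2", call. = FALSE)
  if (jitterMm < 0) stop("jitterMm must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  targets <- vector("list", nRep)
  for (r in seq_len(nRep)) {
    jit <- function(n) stats::runif(n, -jitterMm, jitterMm)
    lm <- LandmarkSet(ac = landmarks@ac + jit(3L),
                      pc = landmarks@pc + jit(3L),
                      thalamusHeightMm = landmarks@thalamusHeightMm,
                      wallXMm = pmax(landmarks@wallXMm + jit(2L), 0),
                      hemisphere = landmarks@hemisphere)
    targets[[r]] <- constructGuiotTarget(lm, params, hemisphere, grid)
  }
  new("TargetingSession", targets = targets, grid = grid,
      jitterMm = jitterMm, seed = as.integer(seed))
}

#' Reproducibility of a targeting session
#'
#' Euclidean distances between the quantized (voxel-center) target points,
#' taking the first target as reference — distances are reported in whole
#' multiples of the voxel geometry because repeated clinical constructions
#' are compared voxel-wise.
#'
#' @param session a [TargetingSession-class] with at least 2 targets.
#' @return `list(distances_to_first, max_mm, mean_mm)`; `distances_to_first`
#'   has one entry per target (the first is 0).
#' @export
targetingReproducibility <- function(session) {
  pts <- t(vapply(session@targets, function(t) t@quantizedPoint,
                  numeric(3L)))
  if (nrow(pts) < 2L) stop("need at least 2 targets", call. = FALSE)
  if (anyNA(pts)) stop("session targets were not quantized", call. = FALSE)
  d <- sqrt(rowSums(sweep(pts, 2L, pts[1L, ], `-`)^2))
  list(distances_to_first = d, max_mm = max(d), mean_mm = mean(d))
}

#' Spherical ROI around a point
#'
#' Voxels whose centers lie within `radiusMm` of `center` — the package's
#' stand-in for the 2 mm radiosurgical isodose sphere drawn around a target.
#'
#' @param center world mm point.
#' @param radiusMm sphere radius (> 0).
#' @param grid a [VoxelGrid-class].
#' @return An [ROIMask-class] (warns if no voxel center falls inside).
#' @export
sphereROI <- function(center, radiusMm, grid) {
  if (radiusMm <= 0) stop("radiusMm must be > 0", call. = FALSE)
  data <- ellipsoidArray(center, rep(radiusMm, 3L), grid)
  if (!any(data)) warning("sphere contains no voxel centers")
  ROIMask(data, grid)
}
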