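# Multi-atlas segmentation: thalamic VOI extraction, decile-landmark
# intensity standardization, weighted label fusion (majority, locally
# weighted, and joint dependency-matrix weighting), and a leave-one-out
# evaluation harness. Registration is out of scope: phantom cohorts share
# one grid, so atlases are "registered" by construction.

#' Voxel bounding box of a mask, dilated by a margin
#'
#' @param mask a nonempty [ROIMask-class].
#' @param marginMm margin added on every side, mm (>= 0); converted to
#'   voxels with `ceiling(margin / spacing)` and clipped at the grid edge.
#' @return `list(lo, hi)` of 1-based voxel index triples.
#' @export
voiBox <- function(mask, marginMm = 2) {
  if (marginMm < 0) stop("marginMm must be >= 0", call. = FALSE)
  if (voxelCount(mask) == 0L) stop("mask is empty", call. = FALSE)
  idx <- which(mask@data != 0, arr.ind = TRUE)
  mvox <- ceiling(marginMm / mask@grid@spacing - 1e-9)
  lo <- pmax(apply(idx, 2L, min) - mvox, 1L)
  hi <- pmin(apply(idx, 2L, max) + mvox, mask@grid@shape)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Crop a volume to a voxel box
#'
#' The cropped grid's origin keeps world coordinates intact, so a VOI voxel
#' maps back to its original world position with no extra bookkeeping.
#'
#' @param vol an [IntensityVolume-class], [ROIMask-class] or
#'   [LabelVolume-class].
#' @param box `list(lo, hi)` as returned by [voiBox()].
#' @return A volume of the same class on the cropped grid.
#' @export
cropVolume <- function(vol, box) {
  g <- vol@grid
  newGrid <- VoxelGrid(box$hi - box$lo + 1L, g@spacing,
                       origin = g@origin + (box$lo - 1L) * g@spacing)
  sub <- vol@data[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2],
                  box$lo[3]:box$hi[3], drop = FALSE]
  if (is(vol, "ROIMask")) ROIMask(sub, newGrid)
  else if (is(vol, "LabelVolume")) LabelVolume(sub, newGrid, vol@labelMap)
  else IntensityVolume(sub, newGrid)
}

#' Extract the volume of interest around the thalamus
#'
#' Crops an intensity volume to the thalamus bounding box dilated by a
#' margin — the working volume for intensity standardization and fusion.
#'
#' @param intensity an [IntensityVolume-class].
#' @param thalamusMask a nonempty [ROIMask-class] on the same grid.
#' @param marginMm dilation margin, mm (default 2).
#' @return An [IntensityVolume-class] on the cropped grid.
#' @export
extractVOI <- function(intensity, thalamusMask, marginMm = 2) {
  stopIfGridMismatch(intensity, thalamusMask)
  cropVolume(intensity, voiBox(thalamusMask, marginMm))
}

voiLandmarks <- function(voi, mask, percentiles) {
  vals <- if (is.null(mask)) as.vector(voi@data) else voi@data[mask@data != 0]
  if (length(vals) < 100L)
    stop("fewer than 100 masked voxels; percentile landmarks are unstable",
         call. = FALSE)
  stats::quantile(vals, percentiles / 100, names = FALSE, type = 7)
}

#' Build the standard intensity scale from a training cohort
#'
#' Computes robust percentile landmarks (p1, the deciles p10..p90, p99)
#' within each training VOI's mask, averages the landmark vectors, and maps
#' the mean vector affinely onto the standard range `[sMin, sMax]`.
#'
#' @param vois list of [IntensityVolume-class] VOIs (>= 1).
#' @param masks optional list of [ROIMask-class] (same length; NULL entries
#'   or `masks = NULL` use every voxel).
#' @param sMin,sMax ends of the standard range (defaults 0, 100).
#' @param percentiles percentile levels in percent (default p1, deciles,
#'   p99).
#' @return A [StandardScale-class].
#' @export
buildStandardScale <- function(vois, masks = NULL, sMin = 0, sMax = 100,
                               percentiles = c(1, seq(10, 90, 10), 99)) {
  if (!length(vois)) stop("need at least one VOI", call. = FALSE)
  lms <- vapply(seq_along(vois), function(i)
    voiLandmarks(vois[[i]], if (is.null(masks)) NULL else masks[[i]],
                 percentiles),
    numeric(length(percentiles)))
  m <- rowMeans(lms)
  k <- length(m)
  if (!(m[k] > m[1]))
    stop("degenerate landmarks (constant intensities)", call. = FALSE)
  new("StandardScale", percentiles = percentiles,
      landmarks = sMin + (m - m[1]) / (m[k] - m[1]) * (sMax - sMin),
      sMin = sMin, sMax = sMax)
}

# Piecewise-linear landmark map with linear extrapolation from the terminal
# segments.
mapPiecewiseLinear <- function(vals, x, y) {
  k <- length(x)
  out <- stats::approx(x, y, xout = vals, rule = 2, ties = "ordered")$y
  s1 <- (y[2] - y[1]) / (x[2] - x[1])
  sk <- (y[k] - y[k - 1]) / (x[k] - x[k - 1])
  low <- vals < x[1]; high <- vals > x[k]
  out[low] <- y[1] + (vals[low] - x[1]) * s1
  out[high] <- y[k] + (vals[high] - x[k]) * sk
  out
}

#' Standardize a VOI's intensities onto the standard scale
#'
#' One-to-one piecewise-linear mapping sending the VOI's own percentile
#' landmarks onto the scale's landmarks; values beyond p1/p99 are linearly
#' extrapolated from the terminal segments. The map is monotone
#' non-decreasing, and exactly undoes any global affine intensity transform
#' of the input (the landmarks transform with the data).
#'
#' @param voi an [IntensityVolume-class].
#' @param scale a [StandardScale-class].
#' @param mask optional [ROIMask-class] over which the input landmarks are
#'   estimated (the map is applied to every voxel).
#' @return A standardized [IntensityVolume-class].
#' @export
standardizeIntensities <- function(voi, scale, mask = NULL) {
  x <- voiLandmarks(voi, mask, scale@percentiles)
  if (any(diff(x) <= 0))
    stop("input landmarks are not strictly increasing; cannot build a ",
         "one-to-one intensity mapping", call. = FALSE)
  IntensityVolume(array(mapPiecewiseLinear(as.vector(voi@data), x,
                                           scale@landmarks),
                        dim = dim(voi@data)), voi@grid)
}

# Patch matrix: rows = candidate voxels (linear indices into arr's grid),
# cols = the (2r+1)^3 patch values, zero-padded beyond the VOI edge.
patchMatrix <- function(arr, cand, r) {
  d <- dim(arr)
  if (r == 0L) return(matrix(arr[cand], ncol = 1L))
  pd <- d + 2L * r
  padded <- array(0, dim = pd)
  padded[(r + 1):(r + d[1]), (r + 1):(r + d[2]), (r + 1):(r + d[3])] <- arr
  ai <- arrayInd(cand, d)
  candPad <- (ai[, 1] + r) + (ai[, 2] + r - 1L) * pd[1] +
    (ai[, 3] + r - 1L) * pd[1] * pd[2]
  off <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  offLin <- off[, 1] + off[, 2] * pd[1] + off[, 3] * pd[1] * pd[2]
  matrix(padded[outer(candPad, offLin, `+`)], nrow = length(cand))
}

fusionWeights <- function(Pt, Pa, params) {
  n <- length(Pa)
  C <- nrow(Pt)
  if (params@method == "local_weighted") {
    msd <- vapply(Pa, function(p) rowMeans((Pt - p)^2), numeric(C))
    msd <- matrix(msd, nrow = C)
    w <- exp(-params@beta * (msd - apply(msd, 1L, min)))
    w / rowSums(w)
  } else {  # joint
    D <- lapply(Pa, function(p) abs(Pt - p))
    M <- array(0, dim = c(C, n, n))
    for (i in seq_len(n)) for (j in i:n) {
      mij <- rowMeans(D[[i]] * D[[j]])
      M[, i, j] <- mij
      M[, j, i] <- mij
    }
    one <- rep(1, n)
    w <- matrix(0, C, n)
    for (cidx in seq_len(C)) {
      Mi <- matrix(M[cidx, , ], n, n) + params@epsilon * diag(n)
      wi <- solve(Mi, one)
      w[cidx, ] <- wi / sum(wi)
    }
    w
  }
}

#' Fuse atlas labels onto a target volume
#'
#' Propagated atlas labels are combined into a per-voxel fused probability
#' and a decision mask. `"majority"` is an unweighted vote; `"local_weighted"`
#' weights atlas i at voxel v by `exp(-beta * MSD_i(v))` where MSD is the
#' mean squared difference between the target and atlas patches around v
#' (weights renormalized per voxel); `"joint"` solves
#' `w = (M + eps I)^-1 1`, normalized to sum 1, where
#' `M_ij(v)` is the patchwise mean product of the absolute intensity
#' differences of atlases i and j against the target, so that correlated
#' atlas errors share the blame. At voxels where all atlases agree, the
#' fused probability equals the consensus label exactly for every method
#' (weights sum to 1), so weights are only solved where atlases disagree
#' unless `returnWeights = TRUE`.
#'
#' @param target the target [IntensityVolume-class] (standardized VOI).
#' @param atlases list of [AtlasCase-class] on the target grid (>= 1).
#' @param params a [FusionParams-class].
#' @param returnWeights also return the full per-voxel weight matrix
#'   (voxels x atlases); intended for small volumes.
#' @return `list(mask, probability, weights)`: the decision
#'   [ROIMask-class] (`probability >= threshold`), the fused-probability
#'   [IntensityVolume-class], and the weights (NULL unless requested).
#' @seealso [looExperiment()]
#' @export
fuseLabels <- function(target, atlases, params = FusionParams(),
                       returnWeights = FALSE) {
  if (!length(atlases)) stop("need at least one atlas", call. = FALSE)
  for (a in atlases) {
    stopIfGridMismatch(target, a@intensity)
    stopIfGridMismatch(target, a@label)
  }
  n <- length(atlases)
  labs <- lapply(atlases, function(a) a@label@data)
  labSum <- Reduce(`+`, labs)
  d <- dim(target@data)
  p <- array(as.numeric(labSum == n), dim = d)  # consensus probabilities

  if (params@method == "majority") {
    p <- labSum / n
    weights <- if (returnWeights)
      matrix(1 / n, prod(d), n) else NULL
  } else {
    cand <- if (returnWeights) seq_len(prod(d)) else
      which(labSum > 0L & labSum < n)
    weights <- NULL
    if (length(cand)) {
      r <- params@patchRadius
      Pt <- patchMatrix(target@data, cand, r)
      Pa <- lapply(atlases, function(a) patchMatrix(a@intensity@data,
                                                    cand, r))
      w <- fusionWeights(Pt, Pa, params)
      lmat <- vapply(labs, function(l) as.numeric(l[cand]),
                     numeric(length(cand)))
      # joint weights may be negative (anti-correlated atlas errors); the
      # fused value is still a probability estimate, so clip it to [0, 1]
      p[cand] <- pmin(pmax(rowSums(w * matrix(lmat, nrow = length(cand))),
                           0), 1)
      if (returnWeights) weights <- w
    }
  }
  list(mask = ROIMask(p >= params@threshold, target@grid),
       probability = IntensityVolume(p, target@grid),
       weights = weights)
}

#' Leave-one-out multi-atlas evaluation on a phantom cohort
#'
#' For each subject and hemisphere: crop every subject's intensity, thalamus
#' and Vim to the target's thalamic VOI; build the standard intensity scale
#' from the remaining subjects; standardize all VOIs; fuse the remaining
#' subjects' Vim labels onto the target; and score the fused mask against
#' the target's ground-truth Vim with the Dice coefficient. Deterministic
#' given the cohort.
#'
#' @param cohort list of [SyntheticSubject-class] (>= 3).
#' @param params a [FusionParams-class].
#' @param marginMm VOI margin around the thalamus, mm.
#' @param hemispheres which hemispheres to evaluate.
#' @return `list(results, mean_dice, sd_dice)`: a data.frame with one row
#'   per (subject, hemisphere) and its Dice, and the cohort mean and sample
#'   standard deviation.
#' @export
looExperiment <- function(cohort, params = FusionParams(), marginMm = 2,
                          hemispheres = c("left", "right")) {
  if (length(cohort) < 3L)
    stop("leave-one-out needs a cohort of at least 3 subjects",
         call. = FALSE)
  rows <- list()
  for (h in hemispheres) {
    thals <- lapply(cohort, structureMask, "thalamus", h)
    vims <- lapply(cohort, structureMask, "vim", h)
    for (t in seq_along(cohort)) {
      box <- voiBox(thals[[t]], marginMm)
      ints <- lapply(cohort, function(s) cropVolume(s@intensity, box))
      thalV <- lapply(thals, cropVolume, box)
      vimV <- lapply(vims, cropVolume, box)
      train <- setdiff(seq_along(cohort), t)
      scale <- buildStandardScale(ints[train], thalV[train])
      std <- lapply(seq_along(cohort), function(i)
        standardizeIntensities(ints[[i]], scale, thalV[[i]]))
      atlases <- lapply(train, function(i)
        AtlasCase(sprintf("S%d", i), std[[i]], vimV[[i]], h))
      fused <- fuseLabels(std[[t]], atlases, params)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = t, hemisphere = h,
        dice = diceCoefficient(fused$mask, vimV[[t]]))
    }
  }
  results <- do.call(rbind, rows)
  list(results = results, mean_dice = mean(results$dice),
       sd_dice = stats::sd(results$dice))
}
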