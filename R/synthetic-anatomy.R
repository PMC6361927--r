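# Synthetic thalamic-anatomy phantoms.
#
# Structures are ellipsoids: an ovoid thalamus per hemisphere, a
# ventral-lateral (VLV) sub-ellipsoid clipped to the thalamus, and a small
# Vim ellipsoid clipped to the VLV and pinned against its lateral border.
# Only volumes, extents and relative positions are anatomically constrained;
# the ellipsoid shape model is the package's own choice. Darker Vc
# (posterior) and Vo (superior-anterior) slabs around the hyperintense Vim
# reproduce the SWI contrast ordering; the pulvinar carries a
# lateral-dark-to-medial-bright gradient.

# Logical array of voxels whose centers satisfy the ellipsoid inequality.
# Only the ellipsoid's bounding window is evaluated.
ellipsoidArray <- function(center, semiAxes, grid) {
  out <- array(FALSE, dim = grid@shape)
  xs <- axisCoords(grid, 1L); ys <- axisCoords(grid, 2L)
  zs <- axisCoords(grid, 3L)
  ix <- which(abs(xs - center[1]) <= semiAxes[1] + grid@spacing[1])
  iy <- which(abs(ys - center[2]) <= semiAxes[2] + grid@spacing[2])
  iz <- which(abs(zs - center[3]) <= semiAxes[3] + grid@spacing[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(out)
  qx <- ((xs[ix] - center[1]) / semiAxes[1])^2
  qy <- ((ys[iy] - center[2]) / semiAxes[2])^2
  qz <- ((zs[iz] - center[3]) / semiAxes[3])^2
  # snap the quadratic form so voxel centers lying exactly on the surface
  # are included regardless of rounding noise (keeps the mask invariant
  # under mirroring and whole-voxel translation)
  out[ix, iy, iz] <- round(outer(outer(qx, qy, `+`), qz, `+`), 9L) <= 1
  out
}

#' Voxelize an ellipsoid
#'
#' A voxel is included iff its center c satisfies
#' sum(((c - center) / semiAxes)^2) <= 1. The realized volume converges to
#' the analytic 4/3 pi a b c as the spacing shrinks.
#'
#' @param center world mm center.
#' @param semiAxes positive mm triple (x, y, z semi-axes).
#' @param grid a [VoxelGrid-class].
#' @return An [ROIMask-class]; warns when the ellipsoid contains no voxel
#'   center (e.g. entirely outside the grid).
#' @examples
#' m <- ellipsoidMask(c(0, 0, 0), c(2, 2, 2), VoxelGrid(c(24, 24, 24), 0.4))
#' voxelCount(m) * 0.4^3   # close to 4/3 * pi * 8
#' @export
ellipsoidMask <- function(center, semiAxes, grid) {
  if (any(semiAxes <= 0)) stop("semiAxes must be positive", call. = FALSE)
  data <- ellipsoidArray(center, semiAxes, grid)
  if (!any(data)) warning("ellipsoid contains no voxel centers")
  ROIMask(data, grid)
}

phantomStructures <- c("thalamus", "vlv", "vim", "vc", "vo", "pulvinar")

phantomLabelMap <- function() {
  structure(1:12, names = paste(rep(c("left", "right"), each = 6L),
                                phantomStructures, sep = "_"))
}

# Scale an ellipsoid (clipped to clipArr) so its voxelized volume hits
# targetMm3. centerFn(scale) lets the center depend on the scale (used to
# keep the Vim pinned to the lateral VLV border while it grows).
fitClippedEllipsoid <- function(centerFn, semiBase, clipArr, targetMm3,
                                grid, lo = 0.2, hi = 3, iters = 35L) {
  vox <- prod(grid@spacing)
  volAt <- function(s) {
    arr <- ellipsoidArray(centerFn(s), s * semiBase, grid) & clipArr
    list(arr = arr, vol = sum(arr) * vox)
  }
  while (volAt(hi)$vol < targetMm3 && hi < 8) hi <- hi * 1.5
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (volAt(mid)$vol < targetMm3) lo <- mid else hi <- mid
  }
  res <- volAt(hi)
  list(arr = res$arr, scale = hi, volumeMm3 = res$vol)
}

# Base geometry of the right-hemisphere structures (mm, AC-PC frame);
# mirrored in x for the left side. Chosen so that the default-parameter
# Guiot point (|x| = 13, y = -18.75, z = 0 for a 25 mm AC-PC line and a
# 2 mm third-ventricle wall) falls in the inferior ventral part of the Vim.
phantomGeometry <- list(
  thalCenter = c(9.6, -16, 5),
  thalSemi = c(9, 16, 12.6),          # 4/3 pi abc = 7600 mm^3
  vlvOffset = c(3.2, -3, -2),         # lateral, posterior, inferior of thal
  vlvSemi = c(4.3, 9.7, 6.5),         # ~1136 mm^3 unclipped
  vcOffsetFromVim = c(0, NA, 0),      # y filled from the Vim semi-axis
  vcSemi = c(2.6, 1.6, 4.2),
  voOffsetFromVim = c(0, 1.8, 4.4),
  voSemi = c(2.6, 2.0, 2.4),
  puOffsetFrac = c(0, -0.62, 0.16),   # fraction of thalamus semi-axes
  puSemiFrac = c(0.62, 0.42, 0.55),
  acpcMm = 25, wallXMm = 2,
  vesselLengthMm = 24)

#' Generate one synthetic subject
#'
#' Builds both hemispheres' thalamus, VLV and Vim (with the nesting
#' Vim inside VLV inside thalamus holding voxelwise), dark Vc/Vo regions and
#' a pulvinar gradient, an SWI-like intensity volume with additive Gaussian
#' noise and optional dark vessel cylinders, and the stereotactic landmark
#' set. The VLV and Vim are rescaled until their realized (voxel-counted,
#' clipped) volumes hit the per-subject target fractions, and the Vim is
#' pinned against the lateral VLV border. Deterministic for fixed
#' `(spec, seed)`.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer seed.
#' @return A [SyntheticSubject-class].
#' @seealso [generateCohort()], [structureMask()]
#' @examples
#' \donttest{
#' subj <- generateSubject(PhantomSpec(), seed = 7)
#' subj
#' }
#' @export
generateSubject <- function(spec, seed = 1L) {
  validObject(spec)
  set.seed(as.integer(seed))
  grid <- spec@grid
  vox <- prod(grid@spacing)
  geo <- phantomGeometry
  jit <- spec@subjectJitter
  U <- function(n, r) if (r > 0) stats::runif(n, -r, r) else numeric(n)

  # Vim semi-axes: full AP/DV/ML extents halved, in (x=ML, y=AP, z=DV)
  # axis order; scaled later to hit the target fraction.
  vimSemiBase <- c(spec@vimExtentMm[3], spec@vimExtentMm[1],
                   spec@vimExtentMm[2]) / 2

  labels <- array(0L, dim = grid@shape)
  intens <- array(spec@swiParams[["background"]], dim = grid@shape)
  truth <- list()
  thalMaxZ <- -Inf

  for (h in c("left", "right")) {
    s <- if (h == "right") 1 else -1
    mirror <- function(p) p * c(s, 1, 1)
    base <- if (h == "left") 0L else 6L

    tGlobal <- U(3L, jit$translationMm)
    thalVolTarget <- spec@thalamusVolumeMm3 * (1 + U(1L, jit$volumeRel))
    vimFrac <- spec@vimFraction * (1 + U(1L, jit$vimFractionRel))
    vlvFrac <- spec@vlvFraction * (1 + U(1L, jit$vlvFractionRel))
    vlvJit <- U(3L, jit$structureTranslationMm)
    vimJit <- c(0, U(2L, jit$structureTranslationMm))  # x stays pinned
    puJit <- U(3L, jit$structureTranslationMm)

    thalCenter <- mirror(geo$thalCenter) + tGlobal
    thalSemi <- geo$thalSemi *
      (thalVolTarget / (4 / 3 * pi * prod(geo$thalSemi)))^(1 / 3)
    thalArr <- ellipsoidArray(thalCenter, thalSemi, grid)
    thalMm3 <- sum(thalArr) * vox
    thalMaxZ <- max(thalMaxZ, max(axisCoords(grid, 3L)[
      apply(thalArr, 3L, any)]))

    vlvCenter <- thalCenter + mirror(geo$vlvOffset) + vlvJit
    vlvFit <- fitClippedEllipsoid(function(sc) vlvCenter, geo$vlvSemi,
                                  thalArr, vlvFrac * thalMm3, grid)
    vlvArr <- vlvFit$arr
    vlvSemi <- vlvFit$scale * geo$vlvSemi

    # Vim center: y/z from the placement fractions (anterior, superior
    # offsets inside the VLV); x chosen, per scale, so the lateral tip of
    # the ellipsoid overshoots the analytic VLV surface by 0.3 mm -- after
    # clipping, the Vim therefore touches the lateral VLV border.
    vimYZ <- c(spec@vimPlacement[2] * vlvSemi[2] + vimJit[2],
               spec@vimPlacement[3] * vlvSemi[3] + vimJit[3])
    vNorm <- vimYZ[1] / vlvSemi[2]
    wNorm <- vimYZ[2] / vlvSemi[3]
    uSurf <- sqrt(max(1 - vNorm^2 - wNorm^2, 0.05))
    vimCenterFn <- function(sc) {
      cx <- uSurf * vlvSemi[1] - sc * vimSemiBase[1] + 0.3
      vlvCenter + c(s * cx, vimYZ)
    }
    vimFit <- fitClippedEllipsoid(vimCenterFn, vimSemiBase, vlvArr,
                                  vimFrac * thalMm3, grid)
    vimArr <- vimFit$arr
    vimCenter <- vimCenterFn(vimFit$scale)
    vimSemi <- vimFit$scale * vimSemiBase

    vcCenter <- vimCenter + c(0, -(vimSemi[2] + 1.2), 0)
    vcArr <- ellipsoidArray(vcCenter, geo$vcSemi, grid) & vlvArr & !vimArr
    voCenter <- vimCenter + mirror(geo$voOffsetFromVim)
    voArr <- ellipsoidArray(voCenter, geo$voSemi, grid) & vlvArr &
      !vimArr & !vcArr
    puCenter <- thalCenter + mirror(geo$puOffsetFrac * thalSemi) + puJit
    puArr <- ellipsoidArray(puCenter, geo$puSemiFrac * thalSemi, grid) &
      thalArr & !vlvArr

    labels[thalArr] <- base + 1L
    labels[vlvArr] <- base + 2L
    labels[vimArr] <- base + 3L
    labels[vcArr] <- base + 4L
    labels[voArr] <- base + 5L
    labels[puArr] <- base + 6L

    p <- spec@swiParams
    intens[thalArr] <- p[["thalamus"]]
    intens[vlvArr] <- p[["vlv"]]
    intens[vimArr] <- p[["vim"]]
    intens[vcArr] <- p[["vc"]]
    intens[voArr] <- p[["vo"]]
    if (any(puArr)) {
      # lateral (large |x|) dark, medial bright
      xs <- axisCoords(grid, 1L)
      ax <- abs(xs)[which(puArr, arr.ind = TRUE)[, 1L]]
      rng <- range(ax)
      med <- if (diff(rng) > 0) 1 - (ax - rng[1]) / diff(rng) else
        rep(0.5, length(ax))
      intens[puArr] <- p[["pulvinarLateral"]] +
        (p[["pulvinarMedial"]] - p[["pulvinarLateral"]]) * med
    }

    truth[[h]] <- list(
      thalamus_mm3 = thalMm3,
      vlv_mm3 = vlvFit$volumeMm3,
      vlv_pct = 100 * vlvFit$volumeMm3 / thalMm3,
      vim_mm3 = vimFit$volumeMm3,
      vim_pct = 100 * vimFit$volumeMm3 / thalMm3,
      vim_center = vimCenter, vim_semi_axes = vimSemi,
      vlv_center = vlvCenter, vlv_semi_axes = vlvSemi,
      thal_center = thalCenter, thal_semi_axes = thalSemi,
      target_vim_fraction = vimFrac, target_vlv_fraction = vlvFrac)
  }

  vesselArr <- array(FALSE, dim = grid@shape)
  vp <- spec@vesselParams
  if (isTRUE(vp$enabled) && vp$count > 0) {
    for (k in seq_len(vp$count)) {
      side <- if (stats::runif(1L) < 0.5) -1 else 1
      p0 <- c(side * geo$thalCenter[1], geo$thalCenter[2:3]) +
        stats::runif(3L, -8, 8)
      dir <- stats::rnorm(3L); dir <- dir / sqrt(sum(dir^2))
      vesselArr <- vesselArr |
        cylinderArray(p0 - dir * geo$vesselLengthMm / 2, dir,
                      geo$vesselLengthMm, vp$radiusMm, grid)
    }
    intens[vesselArr] <- spec@swiParams[["vessel"]]
  }

  intens <- intens + stats::rnorm(length(intens),
                                  sd = spec@swiParams[["noiseSd"]])
  truth$vessel_mask <- ROIMask(vesselArr, grid)
  truth$seed <- as.integer(seed)

  landmarks <- LandmarkSet(
    ac = c(0, 0, 0), pc = c(0, -geo$acpcMm, 0),
    thalamusHeightMm = thalMaxZ, wallXMm = rep(geo$wallXMm, 2L))

  new("SyntheticSubject",
      labels = LabelVolume(labels, grid, phantomLabelMap()),
      intensity = IntensityVolume(intens, grid),
      landmarks = landmarks, spec = spec, truth = truth)
}

# Voxels within radiusMm of the segment p0 + t*dir, t in [0, lengthMm].
cylinderArray <- function(p0, dir, lengthMm, radiusMm, grid) {
  p1 <- p0 + dir * lengthMm
  lo <- pmin(p0, p1) - radiusMm
  hi <- pmax(p0, p1) + radiusMm
  out <- array(FALSE, dim = grid@shape)
  idx <- lapply(1:3, function(a) {
    co <- axisCoords(grid, a)
    which(co >= lo[a] & co <= hi[a])
  })
  if (!all(lengths(idx) > 0)) return(out)
  pts <- as.matrix(expand.grid(
    x = axisCoords(grid, 1L)[idx[[1]]],
    y = axisCoords(grid, 2L)[idx[[2]]],
    z = axisCoords(grid, 3L)[idx[[3]]]))
  rel <- sweep(pts, 2L, p0, `-`)
  t <- pmin(pmax(as.vector(rel %*% dir), 0), lengthMm)
  perp2 <- rowSums((rel - outer(t, dir))^2)
  inside <- array(perp2 <= radiusMm^2, dim = lengths(idx))
  out[idx[[1]], idx[[2]], idx[[3]]] <- inside
  out
}

#' Generate a phantom cohort
#'
#' Per-subject seeds are derived deterministically from the master seed, so
#' the cohort is bitwise reproducible; inter-subject variability comes from
#' the spec's `subjectJitter` ranges.
#'
#' @param spec a [PhantomSpec-class].
#' @param n number of subjects (>= 1).
#' @param seed master integer seed.
#' @return A list of [SyntheticSubject-class] objects.
#' @export
generateCohort <- function(spec, n, seed = 1L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) generateSubject(spec, seeds[i]))
}

#' Extract a structure mask from a synthetic subject
#'
#' Labels store each voxel's finest structure, so nested masks are rebuilt
#' here: `"vlv"` is the union of the VLV-generic, Vim, Vc and Vo labels, and
#' `"thalamus"` the union of all six structure labels of the hemisphere.
#'
#' @param subject a [SyntheticSubject-class].
#' @param structure one of `"thalamus"`, `"vlv"`, `"vim"`, `"vc"`, `"vo"`,
#'   `"pulvinar"`.
#' @param hemisphere `"left"` or `"right"`.
#' @return An [ROIMask-class].
#' @export
structureMask <- function(subject, structure = phantomStructures,
                          hemisphere = c("left", "right")) {
  structure <- match.arg(structure)
  hemisphere <- match.arg(hemisphere)
  base <- if (hemisphere == "left") 0L else 6L
  codes <- base + switch(structure,
    thalamus = 1:6, vlv = 2:5, vim = 3L, vc = 4L, vo = 5L, pulvinar = 6L)
  d <- subject@labels@data
  ROIMask(array(d %in% codes, dim = dim(d)), subject@labels@grid)
}
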