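# Coordinate transforms between 1-based voxel indices and world mm.

#' Voxel/world coordinate transforms
#'
#' Grids are axis-aligned: the world coordinate of 1-based voxel (i, j, k) is
#' `origin + (i-1, j-1, k-1) * spacing`. `voxelToWorld()` maps voxel indices
#' to the world mm of their centers; `worldToVoxel()` maps world points to the
#' nearest voxel index (not clamped to the grid); `snapToGrid()` returns the
#' world coordinates of the nearest in-grid voxel center.
#'
#' @param grid a [VoxelGrid-class].
#' @param ijk integer voxel indices, a length-3 vector or an n x 3 matrix.
#' @param xyz world mm points, a length-3 vector or an n x 3 matrix.
#' @return A vector or matrix matching the input shape.
#' @examples
#' g <- VoxelGrid(c(10, 10, 10), 0.4, origin = c(0, 0, 0))
#' voxelToWorld(g, c(2, 1, 1))   # c(0.4, 0, 0)
#' worldToVoxel(g, c(0.41, 0, 0))
#' @export
voxelToWorld <- function(grid, ijk) {
  if (is.matrix(ijk))
    sweep(sweep(ijk - 1, 2L, grid@spacing, `*`), 2L, grid@origin, `+`)
  else
    grid@origin + (ijk - 1) * grid@spacing
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(grid, xyz) {
  if (is.matrix(xyz)) {
    v <- sweep(xyz, 2L, grid@origin, `-`)
    round(sweep(v, 2L, grid@spacing, `/`)) + 1
  } else {
    round((xyz - grid@origin) / grid@spacing) + 1
  }
}

#' @rdname voxelToWorld
#' @export
snapToGrid <- function(grid, xyz) {
  ijk <- worldToVoxel(grid, xyz)
  ijk <- pmin(pmax(ijk, 1), if (is.matrix(ijk))
    matrix(grid@shape, nrow(ijk), 3L, byrow = TRUE) else grid@shape)
  voxelToWorld(grid, ijk)
}

# World coordinates of voxel centers along one axis.
axisCoords <- function(grid, axis) {
  grid@origin[axis] + (seq_len(grid@shape[axis]) - 1) * grid@spacing[axis]
}

# n x 3 world coordinates of the nonzero voxels of an array.
maskCoords <- function(grid, data) {
  idx <- which(data != 0, arr.ind = TRUE)
  voxelToWorld(grid, idx)
}

sameGrid <- function(a, b, tol = 1e-6) {
  identical(a@shape, b@shape) &&
    max(abs(a@spacing - b@spacing)) < tol &&
    max(abs(a@origin - b@origin)) < tol
}

stopIfGridMismatch <- function(a, b) {
  if (!sameGrid(voxelGrid(a), voxelGrid(b)))
    stop("volumes are defined on different grids", call. = FALSE)
  invisible(TRUE)
}

# Boundary voxels under 6-connectivity: mask voxels with at least one
# face-neighbour outside the mask (the grid edge counts as outside).
boundaryArray <- function(data) {
  m <- data != 0
  d <- dim(m)
  interior <- array(TRUE, d)
  shift_and <- function(acc, ax, by) {
    n <- d[ax]
    idx <- rep(list(quote(expr = )), 3L)
    src <- idx; dst <- idx
    if (by == 1L) { dst[[ax]] <- seq_len(n - 1L); src[[ax]] <- 2:n }
    else          { dst[[ax]] <- 2:n; src[[ax]] <- seq_len(n - 1L) }
    nb <- array(FALSE, d)
    nb <- do.call(`[<-`, c(list(nb), dst, list(
      do.call(`[`, c(list(m), src, list(drop = FALSE))))))
    acc & nb
  }
  for (ax in 1:3) for (by in c(1L, -1L))
    interior <- shift_and(interior, ax, by)
  m & !interior
}

# Minimum Euclidean distance between two point sets (n x 3 matrices), chunked.
minPairwiseDistance <- function(a, b) {
  if (nrow(a) > nrow(b)) { tmp <- a; a <- b; b <- tmp }
  bt <- t(b)
  b2 <- colSums(bt^2)
  best <- Inf
  chunk <- max(1L, floor(2e7 / nrow(b)))
  for (s in seq(1L, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    aa <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), b2, `+`) - 2 * aa %*% bt
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}
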