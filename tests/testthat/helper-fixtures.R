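# Shared fixtures and independent oracles. Phantom subjects are memoized so
# several test files can reuse one generation.

.fixtures <- new.env(parent = emptyenv())

defaultSubject <- function(seed = 7) {
  key <- paste0("subject", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generateSubject(PhantomSpec(), seed = seed)
  .fixtures[[key]]
}

zeroJitterSpec <- function(...) {
  PhantomSpec(subjectJitter = list(translationMm = 0,
                                   structureTranslationMm = 0,
                                   volumeRel = 0, vimFractionRel = 0,
                                   vlvFractionRel = 0), ...)
}

table1Path <- function() system.file("extdata", "table1.csv",
                                     package = "vimloc")

# A random nonempty mask with nonzero x and y extents.
randomMask <- function(grid, p = 0.3) {
  repeat {
    d <- array(stats::runif(prod(gridShape(grid))) < p,
               dim = gridShape(grid))
    if (sum(d) >= 2L) {
      idx <- which(d, arr.ind = TRUE)
      if (length(unique(idx[, 1])) > 1L && length(unique(idx[, 2])) > 1L)
        return(ROIMask(d, grid))
    }
  }
}

# Independent voxel-by-voxel classifier for the eight-subregion rule:
# plain scalar loop, no shared code with the package internals.
oracleSubregionArray <- function(mask, hemisphere) {
  d <- arrayData(mask)
  sp <- gridSpacing(mask); or <- gridOrigin(mask)
  idx <- which(d != 0, arr.ind = TRUE)
  w <- cbind(or[1] + (idx[, 1] - 1) * sp[1],
             or[2] + (idx[, 2] - 1) * sp[2],
             or[3] + (idx[, 3] - 1) * sp[3])
  lo <- apply(w, 2L, min); hi <- apply(w, 2L, max)
  cen <- (lo + hi) / 2; half <- (hi - lo) / 2
  codes <- c("superior-anterior" = 1L, "inferior-anterior" = 2L,
             "superior-lateral" = 3L, "inferior-lateral" = 4L,
             "superior-posterior" = 5L, "inferior-posterior" = 6L,
             "superior-ventral" = 7L, "inferior-ventral" = 8L)
  out <- array(0L, dim = dim(d))
  for (i in seq_len(nrow(w))) {
    u <- round((w[i, 1] - cen[1]) / half[1], 9L)  # tie snap, as documented
    if (hemisphere == "left") u <- -u
    v <- round((w[i, 2] - cen[2]) / half[2], 9L)
    zlab <- if (round(w[i, 3] - cen[3], 9L) >= 0) "superior" else "inferior"
    q <- if (v > abs(u)) "anterior"
         else if (v < -abs(u)) "posterior"
         else if (u >= 0) "lateral"
         else "ventral"
    out[idx[i, 1], idx[i, 2], idx[i, 3]] <- codes[[paste(zlab, q,
                                                         sep = "-")]]
  }
  out
}

# Map package subregion labels onto the oracle's code numbering.
oracleCodeFor <- function(label) {
  c("superior-anterior" = 1L, "inferior-anterior" = 2L,
    "superior-lateral" = 3L, "inferior-lateral" = 4L,
    "superior-posterior" = 5L, "inferior-posterior" = 6L,
    "superior-ventral" = 7L, "inferior-ventral" = 8L)[[label]]
}

# Brute-force sphere voxel enumeration (independent of sphereROI).
oracleSphereCount <- function(center, radius, grid) {
  sp <- gridSpacing(grid); or <- gridOrigin(grid); sh <- gridShape(grid)
  count <- 0L
  for (i in seq_len(sh[1])) for (j in seq_len(sh[2]))
    for (k in seq_len(sh[3])) {
      p <- or + (c(i, j, k) - 1) * sp
      if (round(sum((p - center)^2) / radius^2, 9L) <= 1)
        count <- count + 1L
    }
  count
}

# Minimal targeting session around precomputed (already quantized) points.
sessionFromPoints <- function(pts) {
  lm <- LandmarkSet(ac = c(0, 12.5, 0), pc = c(0, -12.5, 0),
                    thalamusHeightMm = 16, wallXMm = 2)
  targets <- lapply(seq_len(nrow(pts)), function(i)
    new("GuiotTarget", point = pts[i, ], quantizedPoint = pts[i, ],
        hemisphere = "right", params = GuiotParams(), landmarks = lm))
  new("TargetingSession", targets = targets,
      grid = VoxelGrid(c(10L, 10L, 10L), 0.4), jitterMm = 0, seed = 1L)
}

# Target + atlas set on a small grid for label-fusion tests; the last atlas
# optionally dissents with a disjoint blob.
fusionFixture <- function(seed = 1, nAtlas = 3L, consensus = TRUE) {
  set.seed(seed)
  g <- VoxelGrid(c(10L, 10L, 10L), 0.4)
  target <- IntensityVolume(array(stats::rnorm(1000), c(10, 10, 10)), g)
  blob <- array(0L, c(10, 10, 10)); blob[4:6, 4:6, 4:6] <- 1L
  atlases <- lapply(seq_len(nAtlas), function(i) {
    lab <- blob
    if (!consensus && i == nAtlas) {
      lab <- array(0L, c(10, 10, 10)); lab[7:8, 7:8, 7:8] <- 1L
    }
    AtlasCase(paste0("A", i),
              IntensityVolume(arrayData(target) +
                                array(stats::rnorm(1000, sd = 0.3),
                                      c(10, 10, 10)), g),
              ROIMask(lab, g), "left")
  })
  list(grid = g, target = target, atlases = atlases, blob = blob)
}

# A small intensity VOI with smooth structure plus noise, for
# standardization and fusion tests.
smallIntensityVOI <- function(seed = 1, shape = c(12L, 12L, 12L)) {
  set.seed(seed)
  g <- VoxelGrid(shape, 0.4)
  base <- array(0, dim = shape)
  for (i in seq_len(shape[1])) base[i, , ] <- i
  IntensityVolume(base * 10 + array(stats::rnorm(prod(shape), sd = 2),
                                    dim = shape), g)
}
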