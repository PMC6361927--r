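midLandmarks <- function() {
  LandmarkSet(ac = c(0, 12.5, 0), pc = c(0, -12.5, 0),
              thalamusHeightMm = 16, wallXMm = 2)
}

test_that("the Guiot construction places the target deterministically", {
  t <- constructGuiotTarget(midLandmarks(), hemisphere = "right")
  expect_equal(t@point, c(2 + 11, -12.5 + 0.25 * 25, 0))
  l <- constructGuiotTarget(midLandmarks(), hemisphere = "left")
  expect_equal(l@point, c(-13, -6.25, 0))
  # idempotent / deterministic
  expect_equal(constructGuiotTarget(midLandmarks(),
                                    hemisphere = "right")@point, t@point)
})

test_that("the construction is linear in the landmarks and mirror-symmetric", {
  base <- constructGuiotTarget(midLandmarks(), hemisphere = "right")@point
  shift <- c(0.7, -1.1, 0.5)
  lmT <- LandmarkSet(ac = c(0, 12.5, 0) + shift, pc = c(0, -12.5, 0) + shift,
                     thalamusHeightMm = 16,
                     wallXMm = 2 + shift[1])  # wall plane moves with +x
  shifted <- constructGuiotTarget(lmT, hemisphere = "right")@point
  expect_equal(shifted, base + shift)

  left <- constructGuiotTarget(midLandmarks(), hemisphere = "left")@point
  expect_equal(left, base * c(-1, 1, 1))
})

test_that("hemisphere handling is strict", {
  lmL <- LandmarkSet(ac = c(0, 12.5, 0), pc = c(0, -12.5, 0),
                     thalamusHeightMm = 16, wallXMm = 2,
                     hemisphere = "left")
  expect_error(constructGuiotTarget(lmL, hemisphere = "right"),
               "left hemisphere")
  expect_error(constructGuiotTarget(midLandmarks()), "which side")
})

test_that("repeated targeting without jitter is perfectly reproducible", {
  g <- VoxelGrid(c(96L, 96L, 96L), 0.4)
  s <- simulateRepeatedTargeting(midLandmarks(), GuiotParams(), g,
                                 nRep = 6, jitterMm = 0, seed = 2,
                                 hemisphere = "right")
  rep <- targetingReproducibility(s)
  expect_equal(rep$distances_to_first, rep(0, 6))
  expect_equal(rep$max_mm, 0)
  expect_error(simulateRepeatedTargeting(midLandmarks(), GuiotParams(), g,
                                         nRep = 1, hemisphere = "right"),
               ">= 2")
  expect_error(simulateRepeatedTargeting(midLandmarks(), GuiotParams(), g,
                                         jitterMm = -0.1,
                                         hemisphere = "right"), ">= 0")
})

test_that("half-voxel jitter moves quantized points by at most one voxel", {
  g <- VoxelGrid(c(96L, 96L, 96L), 0.4)
  for (seed in 1:20) {
    s <- simulateRepeatedTargeting(midLandmarks(), GuiotParams(), g,
                                   nRep = 6, jitterMm = 0.2, seed = seed,
                                   hemisphere = "right")
    pts <- t(vapply(s@targets, function(t) t@quantizedPoint, numeric(3)))
    vox <- worldToVoxel(g, pts)
    for (ax in 1:3)
      expect_lte(diff(range(vox[, ax])), 1)
  }
})

test_that("distance-to-first reproducibility arithmetic is exact", {
  s <- sessionFromPoints(rbind(c(0, 0, 0), c(0.4, 0.4, 0.4)))
  rep <- targetingReproducibility(s)
  expect_equal(rep$distances_to_first[2], sqrt(3 * 0.16), tolerance = 1e-12)

  pts <- rbind(c(0, 0, 0), c(0.4, 0, 0), c(0, 0, 0), c(0, 0, 0),
               c(0, 0, 0), c(0, 0, 0))
  rep2 <- targetingReproducibility(sessionFromPoints(pts))
  expect_equal(rep2$max_mm, 0.4)
  expect_equal(rep2$mean_mm, 0.4 / 6, tolerance = 1e-12)
})

test_that("sphere ROIs match brute-force enumeration and lattice shifts", {
  g <- VoxelGrid(c(15L, 15L, 15L), 0.4, origin = c(-2.8, -2.8, -2.8))
  s <- sphereROI(c(0, 0, 0), 2, g)
  expect_identical(voxelCount(s), oracleSphereCount(c(0, 0, 0), 2, g))
  expect_lt(abs(voxelCount(s) * 0.4^3 - 33.51) / 33.51, 0.05)

  g2 <- VoxelGrid(c(31L, 31L, 31L), 0.4, origin = c(-6, -6, -6))
  c0 <- voxelCount(sphereROI(c(0, 0, 0), 2, g2))
  cShift <- voxelCount(sphereROI(c(0.8, -1.2, 0.4), 2, g2))  # whole voxels
  expect_identical(c0, cShift)

  small <- sphereROI(c(0, 0, 0), 0.15, g)  # radius < half spacing
  expect_identical(voxelCount(small), 1L)
  expect_error(sphereROI(c(0, 0, 0), -1, g), "> 0")
})
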