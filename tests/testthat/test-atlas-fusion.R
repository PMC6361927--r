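test_that("VOI extraction crops to the dilated bounding box with offsets", {
  g <- VoxelGrid(c(30L, 30L, 30L), 0.4, origin = c(-6, -6, -6))
  d <- array(0L, c(30, 30, 30)); d[10:20, 12:18, 8:22] <- 1L
  thal <- ROIMask(d, g)
  intens <- IntensityVolume(array(stats::rnorm(30^3), c(30, 30, 30)), g)

  voi0 <- extractVOI(intens, thal, marginMm = 0)
  expect_identical(gridShape(voi0), c(11L, 7L, 15L))

  voi2 <- extractVOI(intens, thal, marginMm = 2)  # 5 voxels at 0.4 mm
  expect_identical(gridShape(voi2), c(21L, 17L, 25L))

  # a VOI voxel keeps its world coordinate
  box <- voiBox(thal, 2)
  expect_equal(voxelToWorld(voxelGrid(voi2), c(1, 1, 1)),
               voxelToWorld(g, box$lo))
  expect_equal(arrayData(voi2)[1, 1, 1],
               arrayData(intens)[box$lo[1], box$lo[2], box$lo[3]])

  expect_error(extractVOI(intens, thal, marginMm = -1), ">= 0")
})

test_that("the standard scale averages cohort landmarks onto [sMin, sMax]", {
  voi <- smallIntensityVOI(1)
  sc <- buildStandardScale(list(voi))
  lm <- vimloc:::voiLandmarks(voi, NULL, sc@percentiles)
  k <- length(lm)
  expect_equal(sc@landmarks, (lm - lm[1]) / (lm[k] - lm[1]) * 100)

  # a global intensity shift of one training VOI does not change the scale
  shifted <- IntensityVolume(arrayData(voi) + 37, voxelGrid(voi))
  sc2 <- buildStandardScale(list(voi, shifted))
  expect_equal(sc2@landmarks, sc@landmarks, tolerance = 1e-12)

  tiny <- IntensityVolume(array(1:27 + 0, c(3, 3, 3)),
                          VoxelGrid(c(3L, 3L, 3L), 0.4))
  expect_error(buildStandardScale(list(tiny)), "fewer than 100")
  flat <- IntensityVolume(array(5, c(6, 6, 6)), VoxelGrid(c(6L, 6L, 6L), 0.4))
  expect_error(buildStandardScale(list(flat)), "degenerate|strictly")
})

test_that("standardization is identity on already-standard inputs", {
  voi <- smallIntensityVOI(2)
  lm <- vimloc:::voiLandmarks(voi, NULL, c(1, seq(10, 90, 10), 99))
  sc <- buildStandardScale(list(voi), sMin = lm[1], sMax = lm[length(lm)])
  out <- standardizeIntensities(voi, sc)
  expect_equal(arrayData(out), arrayData(voi), tolerance = 1e-10)
})

test_that("standardization cancels global affine intensity transforms", {
  voi <- smallIntensityVOI(3)
  sc <- buildStandardScale(list(smallIntensityVOI(4), smallIntensityVOI(5)))
  ref <- standardizeIntensities(voi, sc)
  aff <- IntensityVolume(2.5 * arrayData(voi) - 40, voxelGrid(voi))
  out <- standardizeIntensities(aff, sc)
  expect_equal(arrayData(out), arrayData(ref), tolerance = 1e-6)
})

test_that("standardization preserves intensity ordering", {
  voi <- smallIntensityVOI(6)
  sc <- buildStandardScale(list(smallIntensityVOI(7)))
  out <- standardizeIntensities(voi, sc)
  o <- order(as.vector(arrayData(voi)))
  expect_true(!is.unsorted(as.vector(arrayData(out))[o]))
})

test_that("consensus atlases reproduce their label under every method", {
  fx <- fusionFixture(consensus = TRUE)
  for (m in c("majority", "local_weighted", "joint")) {
    fused <- fuseLabels(fx$target, fx$atlases, FusionParams(method = m))
    expect_identical(arrayData(fused$mask), fx$blob, info = m)
  }
})

test_that("majority voting counts labels", {
  fx <- fusionFixture(nAtlas = 3L, consensus = FALSE)
  fused <- fuseLabels(fx$target, fx$atlases,
                      FusionParams(method = "majority"))
  expect_equal(arrayData(fused$probability)[5, 5, 5], 2 / 3)
  expect_identical(arrayData(fused$mask)[5, 5, 5], 1L)   # 2/3 >= 0.5
  expect_equal(arrayData(fused$probability)[8, 8, 8], 1 / 3)
  expect_identical(arrayData(fused$mask)[8, 8, 8], 0L)
})

test_that("a perfectly matching atlas dominates local weighting", {
  set.seed(2)
  g <- VoxelGrid(c(10L, 10L, 10L), 0.4)
  target <- IntensityVolume(array(stats::rnorm(1000), c(10, 10, 10)), g)
  lab1 <- array(0L, c(10, 10, 10)); lab1[4:6, 4:6, 4:6] <- 1L
  lab2 <- array(0L, c(10, 10, 10)); lab2[7:8, 4:6, 4:6] <- 1L
  a1 <- AtlasCase("same", target, ROIMask(lab1, g), "left")
  a2 <- AtlasCase("far",
                  IntensityVolume(arrayData(target) +
                                    array(stats::rnorm(1000, mean = 3),
                                          c(10, 10, 10)), g),
                  ROIMask(lab2, g), "left")
  fused <- fuseLabels(target, list(a1, a2),
                      FusionParams(method = "local_weighted", beta = 5))
  expect_identical(arrayData(fused$mask), lab1)
})

test_that("fused probabilities are proper and weights sum to one", {
  fx <- fusionFixture(nAtlas = 4L, consensus = FALSE)
  for (m in c("majority", "local_weighted", "joint")) {
    fused <- fuseLabels(fx$target, fx$atlases, FusionParams(method = m),
                        returnWeights = TRUE)
    p <- arrayData(fused$probability)
    expect_true(all(p >= -1e-9 & p <= 1 + 1e-9), info = m)
    expect_equal(rowSums(fused$weights), rep(1, length(p)),
                 tolerance = 1e-9, info = m)
  }
})

test_that("local weighting degenerates to majority as beta -> 0", {
  fx <- fusionFixture(nAtlas = 3L, consensus = FALSE)
  maj <- fuseLabels(fx$target, fx$atlases, FusionParams(method = "majority"))
  loc <- fuseLabels(fx$target, fx$atlases,
                    FusionParams(method = "local_weighted", beta = 1e-9))
  expect_equal(arrayData(loc$probability), arrayData(maj$probability),
               tolerance = 1e-6)
})

test_that("joint weighting favours the atlas with smaller patch error", {
  set.seed(5)
  g <- VoxelGrid(c(9L, 9L, 9L), 0.4)
  target <- IntensityVolume(array(stats::rnorm(729), c(9, 9, 9)), g)
  lab1 <- array(0L, c(9, 9, 9)); lab1[4:5, 4:5, 4:5] <- 1L
  lab2 <- array(0L, c(9, 9, 9)); lab2[6:7, 4:5, 4:5] <- 1L
  near <- AtlasCase("near",
    IntensityVolume(arrayData(target) + array(stats::rnorm(729, sd = 0.1),
                                              c(9, 9, 9)), g),
    ROIMask(lab1, g), "left")
  far <- AtlasCase("far",
    IntensityVolume(arrayData(target) + array(stats::rnorm(729, sd = 3),
                                              c(9, 9, 9)), g),
    ROIMask(lab2, g), "left")
  fused <- fuseLabels(target, list(near, far),
                      FusionParams(method = "joint"), returnWeights = TRUE)
  expect_gt(mean(fused$weights[, 1]), mean(fused$weights[, 2]))
  # atlases disjoint from the truth yield Dice 0
  truth <- array(0L, c(9, 9, 9)); truth[1:2, 8:9, 8:9] <- 1L
  expect_equal(diceCoefficient(fused$mask, ROIMask(truth, g)), 0)
})

test_that("leave-one-out on an identical cohort is perfect", {
  co <- generateCohort(zeroJitterSpec(
    vesselParams = list(count = 0L, radiusMm = 0.4, enabled = FALSE)),
    3, seed = 11)
  loo <- looExperiment(co, FusionParams(method = "joint"))
  expect_equal(loo$results$dice, rep(1, 6))
  expect_equal(loo$mean_dice, 1)
  expect_error(looExperiment(co[1:2]), "at least 3")
})
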