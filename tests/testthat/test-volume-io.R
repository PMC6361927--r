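test_that("NIfTI round-trip is lossless for labels and masks", {
  g <- VoxelGrid(c(8L, 9L, 10L), c(0.4, 0.4, 0.4), origin = c(-3, 2.5, -1))
  set.seed(11)
  lab <- LabelVolume(array(sample(0:7, 8 * 9 * 10, replace = TRUE),
                           c(8, 9, 10)), g,
                     c(a = 1L, b = 2L, c = 3L, d = 4L, e = 5L, f = 6L,
                       gg = 7L))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(lab, f)
  back <- readVolume(f, kind = "label")
  expect_identical(arrayData(back), arrayData(lab))
  expect_equal(gridSpacing(back), gridSpacing(lab))
  expect_equal(gridOrigin(back), gridOrigin(lab))

  m <- ROIMask(array(sample(c(0, 1), 8 * 9 * 10, replace = TRUE),
                     c(8, 9, 10)), g)
  f2 <- withr::local_tempfile(fileext = ".nii")
  writeVolume(m, f2)
  expect_identical(arrayData(readVolume(f2, kind = "mask")), arrayData(m))
})

test_that("reading a float volume as a mask binarizes nonzero values", {
  g <- VoxelGrid(c(4L, 4L, 4L), 0.4, origin = c(0, 0, 0))
  vals <- array(0, c(4, 4, 4)); vals[1:2, 1, 1] <- 2.0
  f <- withr::local_tempfile(fileext = ".nii")
  writeVolume(IntensityVolume(vals, g), f)
  m <- readVolume(f, kind = "mask")
  expect_s4_class(m, "ROIMask")
  expect_identical(sort(unique(as.vector(arrayData(m)))), c(0L, 1L))
  expect_identical(voxelCount(m), 2L)
})

test_that("rotated or sheared affines are rejected with the affine shown", {
  a <- array(stats::rnorm(4^3), c(4, 4, 4))
  img <- RNifti::asNifti(a)
  th <- 10 * pi / 180
  rot <- diag(4)
  rot[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  RNifti::sform(img) <- structure(rot, code = 2L)
  RNifti::qform(img) <- structure(rot, code = 2L)
  f <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(img, f)
  expect_error(readVolume(f), "not axis-aligned")
  expect_error(readVolume(tempfile(fileext = ".nii")), "not found")
})

test_that("world/voxel transforms are mutual inverses on in-grid voxels", {
  set.seed(3)
  for (rep in 1:5) {
    g <- VoxelGrid(sample(3:12, 3L, replace = TRUE),
                   stats::runif(3, 0.2, 1.1), origin = stats::rnorm(3))
    ijk <- as.matrix(expand.grid(seq_len(gridShape(g)[1]),
                                 seq_len(gridShape(g)[2]),
                                 seq_len(gridShape(g)[3])))
    colnames(ijk) <- NULL
    expect_equal(worldToVoxel(g, voxelToWorld(g, ijk)), ijk)
  }
})

test_that("the packaged cohort table matches the transcribed values", {
  tab <- loadCohortTable(table1Path())
  d <- cohortData(tab)
  expect_identical(nrow(d), 18L)
  expect_identical(sum(!is.na(d$vim_manual_mm3)), 17L)
  ys2l <- d[d$subject_id == "YS2" & d$hemisphere == "left", ]
  expect_equal(ys2l$vim_manual_mm3, 76.3)
  expect_equal(ys2l$vlv_cm3, 1.3)
  es1r <- d[d$subject_id == "ES1" & d$hemisphere == "right", ]
  expect_equal(es1r$vim_manual_mm3, 94.5)
  ys1 <- d[d$subject_id == "YS1", ]
  expect_true(all(is.na(ys1$vim_multiatlas_mm3)))
  expect_true(is.na(ys1$vim_manual_mm3[ys1$hemisphere == "left"]))
})

test_that("cohort table validation catches schema and value errors", {
  d <- cohortData(loadCohortTable(table1Path()))
  tmp <- withr::local_tempfile(fileext = ".csv")

  write.csv(d[0, ], tmp, row.names = FALSE, na = "")
  expect_identical(nrow(cohortData(loadCohortTable(tmp))), 0L)

  bad <- d; bad$vim_manual_mm3[3] <- -1
  write.csv(bad, tmp, row.names = FALSE, na = "")
  expect_error(loadCohortTable(tmp), ">= 0")

  dup <- rbind(d, d[1, ])
  write.csv(dup, tmp, row.names = FALSE, na = "")
  expect_error(loadCohortTable(tmp), "one row per")

  write.csv(d[, -3], tmp, row.names = FALSE, na = "")
  expect_error(loadCohortTable(tmp), "misses columns")
})

test_that("landmark sets survive a JSON round-trip", {
  lm <- LandmarkSet(ac = c(0, 12.5, 0), pc = c(0.2, -12.5, -0.4),
                    thalamusHeightMm = 16.4,
                    wallXMm = c(left = 1.8, right = 2.2))
  f <- withr::local_tempfile(fileext = ".json")
  writeLandmarks(lm, f)
  back <- readLandmarks(f)
  expect_equal(back@ac, lm@ac)
  expect_equal(back@pc, lm@pc)
  expect_equal(back@wallXMm, lm@wallXMm)
  expect_equal(back@thalamusHeightMm, lm@thalamusHeightMm)
})
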