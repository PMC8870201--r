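test_that("volume and mask constructors enforce their invariants", {
  expect_error(image_volume(array(1, c(2, 2)), c(1, 1, 1)), "3D")
  expect_error(image_volume(array(c(1, NA), c(2, 1, 1))), "finite")
  expect_error(image_volume(array(1, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "spacing")
  v <- image_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_equal(length(v$voxels), 64L)
  expect_true(all(v$voxels == 0))
  m <- roi_mask(array(c(0, 3, -2, 0), c(4, 1, 1)))
  expect_equal(as.integer(m$voxels), c(0L, 1L, 1L, 0L))
})

test_that("NIfTI write-then-read round trip preserves voxels and spacing", {
  set.seed(7)
  arr <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  v <- image_volume(arr, spacing = c(0.8, 0.8, 2.0), origin = c(-10, 5, 2),
                    modality = "DWI")
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path, modality = "DWI")
  expect_identical(dim(v2$voxels), dim(arr))
  expect_identical(as.numeric(v2$voxels), as.numeric(arr))  # bit-for-bit
  expect_equal(v2$spacing, c(0.8, 0.8, 2.0), tolerance = 1e-6)
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(2, 2, 2, 2))), p4)
  expect_error(read_volume(p4), "3D")

  m <- roi_mask(array(rbinom(60, 1, 0.4), c(4, 5, 3)), spacing = c(1, 1, 2))
  path2 <- tempfile(fileext = ".nii.gz")
  write_volume(m, path2)
  m2 <- read_mask(path2)
  expect_identical(m2$voxels, m$voxels)
})

test_that("geometry validation names the mismatching field", {
  v <- image_volume(array(0, c(10, 10, 10)))
  m_ok <- roi_mask(array(1, c(10, 10, 10)))
  expect_true(validate_pair(v, m_ok))
  m_shape <- roi_mask(array(1, c(12, 12, 12)))
  expect_error(validate_pair(v, m_shape), "shape")
  m_sp <- roi_mask(array(1, c(10, 10, 10)), spacing = c(1, 1, 1.5))
  expect_error(validate_pair(v, m_sp), "spacing")
})

test_that("Dice coefficient matches voxel-count arithmetic and conventions", {
  zero <- function() array(0L, c(5, 5, 5))
  a <- zero(); a[1:10] <- 1L
  b <- zero(); b[c(1:8, 21:22)] <- 1L   # |A|=10, |B|=10, overlap 8
  expect_equal(dice_coefficient(roi_mask(a), roi_mask(b)), 0.8)
  expect_equal(dice_coefficient(roi_mask(a), roi_mask(a)), 1)
  d <- zero(); d[30:39] <- 1L
  expect_equal(dice_coefficient(roi_mask(a), roi_mask(d)), 0)
  expect_equal(dice_coefficient(roi_mask(zero()), roi_mask(zero())), 1)
  expect_equal(dice_coefficient(roi_mask(zero()), roi_mask(a)), 0)
  expect_error(dice_coefficient(roi_mask(a), roi_mask(array(0L, c(4, 4, 4)))),
               "shape")
})

test_that("Dice is symmetric and bounded over random mask pairs", {
  set.seed(11)
  for (i in 1:25) {
    a <- roi_mask(array(rbinom(64, 1, runif(1, 0.1, 0.9)), c(4, 4, 4)))
    b <- roi_mask(array(rbinom(64, 1, runif(1, 0.1, 0.9)), c(4, 4, 4)))
    d1 <- dice_coefficient(a, b)
    expect_identical(d1, dice_coefficient(b, a))
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
})

test_that("ROI intensities come out in raster order with coordinates", {
  # 3x3x1 checkerboard, mask on the 'white' squares
  vals <- array(1:9, c(3, 3, 1))
  mask <- array(c(1, 0, 1, 0, 1, 0, 1, 0, 1), c(3, 3, 1))
  v <- image_volume(vals); m <- roi_mask(mask)
  out <- roi_intensities(v, m)
  expect_equal(out$values, c(1, 3, 5, 7, 9))  # x fastest, then y
  expect_equal(out$coords[1, ], c(1L, 1L, 1L))
  expect_equal(out$coords[5, ], c(3L, 3L, 1L))

  const <- image_volume(array(7, c(3, 3, 1)))
  expect_true(all(roi_intensities(const, m)$values == 7))
  expect_length(roi_intensities(const, roi_mask(array(c(rep(1, 5), rep(0, 4)),
                                                      c(3, 3, 1))))$values, 5L)
  expect_error(roi_intensities(v, roi_mask(array(0, c(3, 3, 1)))), "empty")
})
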