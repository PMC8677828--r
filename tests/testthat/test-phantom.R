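test_that("cube rasterization reproduces the exact partial-volume arithmetic", {
  spec <- phantom_spec()
  vol <- rasterize_cube(spec)
  expect_identical(dim(vol), c(22L, 22L, 22L))
  expect_identical(length(vol$data), 10648L)
  frac <- vol$data
  ## total volume conserved exactly: 5.6^3 = 175.616 mm^3
  expect_equal(sum(frac) * 0.8^3, 5.6^3)
  ## 6^3 = 216 full voxels, 8^3 - 6^3 = 296 strictly fractional voxels
  expect_identical(sum(frac == 1), 216L)
  expect_identical(sum(frac > 0 & frac < 1), 296L)
  expect_identical(sum(frac > 0), 512L)
})

test_that("rasterization conserves volume for arbitrary offsets and sizes", {
  for (case in list(c(5.6, 0.3), c(4.0, 0.0), c(6.4, 0.71), c(3.3, 0.5))) {
    spec <- phantom_spec(side_mm = case[1], offset_vox = case[2])
    vol <- rasterize_cube(spec)
    expect_equal(sum(vol$data) * 0.8^3, case[1]^3, tolerance = 1e-9)
  }
  ## grid-aligned cube has no partial volume
  v0 <- rasterize_cube(phantom_spec(offset_vox = 0))
  expect_true(all(v0$data %in% c(0, 1)))
  ## a cube too large for the ROI is rejected
  expect_error(phantom_spec(side_mm = 16), "margin")
})

test_that("high-resolution ground truth is exact and grid-aligned", {
  spec <- phantom_spec()
  truth <- ground_truth_mask(spec)
  expect_identical(dim(truth$mask), c(44L, 44L, 44L))
  expect_identical(sum(truth$mask), 2744L) # 14^3
  expect_equal(mask_volume(truth), 175.616)
  expect_equal(dice_coefficient(truth, truth), 1)
  ## margins of at least 4 high-res voxels
  on <- which(truth$mask, arr.ind = TRUE)
  expect_gte(min(on), 5)
  expect_lte(max(on), 40)
  ## an offset not representable on the doubled grid demands a finer grid
  expect_error(ground_truth_mask(phantom_spec(offset_vox = 0.3)),
               "finer truth grid")
})

test_that("gaussian noise is seeded, reproducible, and calibrated", {
  vol <- rasterize_cube(phantom_spec())
  expect_identical(add_gaussian_noise(vol, 0)$data, vol$data)
  a <- add_gaussian_noise(vol, 0.5, seed = 31)
  b <- add_gaussian_noise(vol, 0.5, seed = 31)
  expect_identical(a$data, b$data)
  c <- add_gaussian_noise(vol, 0.5, seed = 32)
  expect_false(identical(a$data, c$data))
  ## sample SD over the 10,648-voxel ROI within 3% of nominal
  noise <- a$data - vol$data
  expect_equal(sd(noise), 0.5, tolerance = 0.03)
})

test_that("half-max segmentation thresholds and keeps the largest component", {
  spec <- phantom_spec()
  vol <- rasterize_cube(spec)
  seg <- segment_halfmax(vol)
  expect_identical(seg$mask, vol$data >= 0.5)
  ## an isolated bright speck smaller than the cube is discarded
  vol2 <- vol
  vol2$data[1, 1, 1] <- 2
  seg2 <- segment_halfmax(vol2)
  expect_identical(seg2$mask, vol$data >= 0.5)
  ## polarity-aware: dark object on bright background
  volneg <- vol; volneg$data <- 1 - volneg$data
  segneg <- segment_halfmax(volneg, background = 1, contrast = -1)
  expect_identical(segneg$mask, seg$mask)
  ## empty foreground is an explicit error
  flat <- volume_grid(array(0, c(5, 5, 5)), 0.8)
  expect_error(segment_halfmax(flat), "empty foreground")
})

test_that("26-connectivity joins diagonal neighbours", {
  a <- array(FALSE, c(4, 4, 4))
  a[1, 1, 1] <- TRUE; a[2, 2, 2] <- TRUE; a[3, 3, 3] <- TRUE # one diagonal chain
  a[1, 4, 1] <- TRUE                                         # separate speck
  lab <- edgeup:::cpp_label_components(a, dim(a))
  expect_identical(lab[1, 1, 1], lab[3, 3, 3])
  expect_false(lab[1, 4, 1] == lab[1, 1, 1])
  expect_identical(sort(unique(as.vector(lab))), c(0L, 1L, 2L))
})

test_that("Dice coefficient follows its definition", {
  mk <- function(a) segmentation_mask(a, 0.8)
  a <- array(FALSE, c(10, 10, 10)); a[2:7, 2:7, 2:7] <- TRUE   # 216 voxels
  b <- array(FALSE, c(10, 10, 10)); b[1:8, 1:8, 1:8] <- TRUE   # 512 voxels
  expect_equal(dice_coefficient(mk(a), mk(b)), 2 * 216 / (216 + 512))
  expect_equal(dice_coefficient(mk(a), mk(a)), 1)
  d <- array(FALSE, c(10, 10, 10)); d[9:10, 9:10, 9:10] <- TRUE
  expect_equal(dice_coefficient(mk(a), mk(d)), 0)
  ## symmetry
  set.seed(2)
  r1 <- mk(array(runif(1000) > 0.5, c(10, 10, 10)))
  r2 <- mk(array(runif(1000) > 0.5, c(10, 10, 10)))
  expect_identical(dice_coefficient(r1, r2), dice_coefficient(r2, r1))
  ## grid mismatch is an error
  expect_error(dice_coefficient(mk(a), segmentation_mask(a, 0.4)),
               "same grid")
})

test_that("mask volume is count times voxel volume", {
  a <- array(FALSE, c(10, 10, 10)); a[2:7, 2:7, 2:7] <- TRUE
  expect_equal(mask_volume(segmentation_mask(a, 0.8)), 110.592)
  b <- array(FALSE, c(10, 10, 10)); b[1:8, 1:8, 1:8] <- TRUE
  expect_equal(mask_volume(segmentation_mask(b, 0.8)), 262.144)
  expect_equal(mask_volume(segmentation_mask(array(FALSE, c(3, 3, 3)), 0.8)), 0)
})

test_that("experiment runners are reproducible and well-formed", {
  lib <- eu_axis_lib()
  out <- withr::local_tempdir()
  r1 <- run_noise_sweep(lib, sigmas = 0.25, iterations = c(0L, 1L),
                        replicates = 2L, seed = 5L, out_dir = out)
  r2 <- run_noise_sweep(lib, sigmas = 0.25, iterations = c(0L, 1L),
                        replicates = 2L, seed = 5L)
  expect_identical(r1$dsc, r2$dsc)
  expect_identical(r1$seed, r2$seed)
  expect_named(r1, c("sigma", "iterations", "replicate", "seed",
                     "volume_mm3", "dsc", "shared_mm3"))
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(file.exists(file.path(out, "summary.csv")))
  summ <- attr(r1, "summary")
  expect_identical(nrow(summ), 2L)
  expect_true(all(r1$dsc >= 0 & r1$dsc <= 1))
  ## different master seed changes the draws
  r3 <- run_noise_sweep(lib, sigmas = 0.25, iterations = 1L,
                        replicates = 2L, seed = 6L)
  expect_false(identical(r3$dsc, r1$dsc[r1$iterations == 1]))
})
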