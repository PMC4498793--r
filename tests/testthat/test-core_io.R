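test_that("NIfTI round trip preserves labels and anisotropic spacing", {
  sp <- phantom_spec(R0 = 8, fold_amp = 0.1, fold_freq = c(4, 4),
                     t_cortex = 2, t_csf = 1.5,
                     spacing = c(0.35, 0.35, 1.2))
  map <- generate_phantom(sp, truth = "none")$map
  path <- tempfile(fileext = ".nii.gz")
  write_label_volume(map, path)
  back <- load_label_volume(path)
  expect_identical(back$values, map$values)
  expect_equal(back$spacing, c(0.35, 0.35, 1.2), tolerance = 1e-6)
})

test_that("unknown labels and malformed volumes are refused with detail", {
  arr <- array(0L, c(4, 4, 4)); arr[2, 2, 2] <- 9L
  img <- RNifti::asNifti(arr)
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, path)
  expect_error(load_label_volume(path), "9")

  arrf <- array(0.5, c(4, 4, 4))
  pathf <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arrf), pathf)
  expect_error(load_label_volume(pathf), "integer")

  arr4 <- array(0L, c(4, 4, 4, 2))
  path4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr4), path4)
  expect_error(load_label_volume(path4), "3D")

  expect_error(tissue_label_map(array(1L, c(3, 3, 3)), c(1, -1, 1)),
               "positive")
})

test_that("custom label schemes recode third-party integer codes", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("UWM: 7", "CoGM: 5", "CSF: 6"), cfg)
  scheme <- read_label_scheme(cfg)
  arr <- array(0L, c(5, 5, 5))
  arr[2:4, 2:4, 2:4] <- 7L; arr[3, 3, 3] <- 5L
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  map <- load_label_volume(path, scheme)
  expect_equal(sum(map$values == 1L), 26)
  expect_equal(sum(map$values == 2L), 1)
})

test_that("nearest-neighbour resampling conserves volume and labels", {
  map <- fixture("resample_ball", ball_map(10, spacing = 1))
  expect_identical(resample_nearest(map, 1)$values, map$values)

  fine <- resample_nearest(map, 0.5)
  v1 <- tissue_volume(map, "UWM")
  v2 <- tissue_volume(fine, "UWM")
  expect_lt(abs(v2 / v1 - 1), 0.01)
  expect_true(all(unique(as.vector(fine$values)) %in%
                    unique(as.vector(map$values))))
  expect_error(resample_nearest(map, 5), "4x")
})
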