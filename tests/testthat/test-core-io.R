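test_that("NIfTI round-trip preserves voxels and geometry", {
  ph <- rasterize_phantom(phantom_spec("straight", length_mm = 30,
                                       spacing_mm = c(0.5, 0.5, 0.5),
                                       seed = 11))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$image, f)
  back <- read_image(f)
  expect_equal(back$spacing, c(0.5, 0.5, 0.5))
  expect_equal(back$origin, ph$image$origin, tolerance = 1e-5)
  expect_equal(as.numeric(back$voxels), as.numeric(ph$image$voxels),
               tolerance = 1e-5)

  fl <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$labels, fl)
  lab <- read_labels(fl, reference = back)
  expect_identical(as.integer(lab$voxels), as.integer(ph$labels$voxels))
  expect_true(all(c("aorta") %in% names(lab$vocabulary)))
})

test_that("NRRD round-trip preserves voxels and geometry", {
  ph <- rasterize_phantom(phantom_spec("straight", length_mm = 25,
                                       spacing_mm = 1, seed = 12))
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(ph$image, f)
  back <- read_image(f)
  expect_equal(back$spacing, ph$image$spacing)
  expect_equal(back$origin, ph$image$origin)
  expect_equal(as.numeric(back$voxels), as.numeric(ph$image$voxels))
})

test_that("reader rejects malformed inputs", {
  expect_error(read_image("does-not-exist.nii.gz"), "not found")
  expect_error(image_volume(matrix(0, 4, 4), c(1, 1, 1)), "non-3D")
  # 2-D NIfTI on disk
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(0, 8, 8)), f)
  expect_error(read_image(f), "non-3D")
  f2 <- withr::local_tempfile(fileext = ".xyz")
  file.create(f2)
  expect_error(read_image(f2), "unrecognized format")
})

test_that("label geometry mismatches and missing structures are reported", {
  ph <- rasterize_phantom(phantom_spec("straight", length_mm = 25,
                                       spacing_mm = 1, seed = 13))
  small <- image_volume(ph$image$voxels[1:10, 1:10, 1:10], ph$image$spacing)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$labels, f)
  expect_error(read_labels(f, reference = small), "geometry mismatch")
  # bare tube: all organ structures missing, recorded rather than zero-filled
  lab <- read_labels(f)
  expect_true("kidney_left" %in% lab$missing)
  expect_false("aorta" %in% lab$missing)
})

test_that("configuration defaults match the protocol and validate inputs", {
  cfg <- load_config()
  expect_equal(cfg$alpha, 3)
  expect_equal(cfg$min_hu, 400)
  expect_equal(cfg$lumen_band, c(5, 3))
  expect_equal(cfg$skeleton_dilation_mm, 1)
  expect_equal(cfg$artery_dilation_mm, 5)
  expect_equal(cfg$distal_arch_offset_mm, 20)
  expect_equal(cfg$root_windows_mm$sinus, 20)
  expect_equal(cfg$root_windows_mm$stj, c(5, 25))
  expect_equal(cfg$root_windows_mm$annulus, 10)

  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"alpha": 5}', f)
  over <- load_config(f)
  expect_equal(over$alpha, 5)
  expect_equal(over$min_hu, 400) # untouched keys keep defaults

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"min_hu": -10}', bad)
  expect_error(load_config(bad), "min_hu")
  expect_error(pipeline_config(cpr_slice_step_mm = -1), "positive")
})
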