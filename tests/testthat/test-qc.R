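test_that("scan classification identifies field of view", {
  fu <- fx_full()
  cls <- classify_scan(structure_mask(fu$ph$labels, "aorta"), fu$ph$labels,
                       fu$ph$image)
  expect_equal(cls$class, "full")
  expect_equal(cls$component_count, 1L)

  ca <- fx_cardiac()
  cls2 <- classify_scan(structure_mask(ca$ph$labels, "aorta"), ca$ph$labels,
                        ca$ph$image)
  expect_equal(cls2$class, "cardiac_two_part")
  expect_equal(cls2$component_count, 2L)

  ab <- fx_abdominal()
  cls3 <- classify_scan(structure_mask(ab$ph$labels, "aorta"), ab$ph$labels,
                        ab$ph$image)
  expect_equal(cls3$class, "abdominal")

  empty <- classify_scan(array(FALSE, dim(fu$ph$image$voxels)), fu$ph$labels,
                         fu$ph$image)
  expect_equal(empty$class, "rejected")
  expect_true(length(empty$reasons) >= 1)
})

test_that("surface-to-volume matches the analytic sphere and flags porosity", {
  sph <- sphere_mask(20, spacing = 1)
  sv <- surface_to_volume_check(sph, c(1, 1, 1), threshold = 0.5)
  expect_lt(abs(sv$ratio_per_mm - 3 / 20) / (3 / 20), 0.15)
  expect_false(sv$flag)

  # salt-and-pepper porous version of the same mask
  set.seed(51)
  holes <- array(runif(length(sph)) < 0.3, dim(sph))
  porous <- sph & !holes
  svp <- surface_to_volume_check(porous, c(1, 1, 1), threshold = 0.5)
  expect_gt(svp$ratio_per_mm, sv$ratio_per_mm)
  expect_true(svp$flag)
  # threshold semantics: a threshold above the measured ratio does not flag
  expect_false(surface_to_volume_check(porous, c(1, 1, 1),
                                       threshold = svp$ratio_per_mm + 1)$flag)
  expect_error(surface_to_volume_check(sph & FALSE, c(1, 1, 1)), "empty")
})

test_that("non-contrast scans are rejected with machine-readable reasons", {
  nc <- fx_noncontrast()
  expect_equal(nc$report$status, "rejected")
  expect_true(any(grepl("surface-to-volume|empty lumen",
                        nc$report$classification$reasons)))
  expect_null(nc$report$measurements)
})
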