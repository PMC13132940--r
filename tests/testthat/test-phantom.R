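test_that("analytic curves have exact lengths and tortuosity", {
  st <- make_curve(phantom_spec("straight", length_mm = 100))
  expect_equal(st$total_length_mm, 100, tolerance = 1e-4)

  sc <- make_curve(phantom_spec("semicircle", arch_radius_mm = 50))
  expect_equal(sc$total_length_mm, pi * 50, tolerance = 1e-3)
  p <- sc$pos(c(0, sc$total_length_mm))
  chord <- sqrt(sum((p[2, ] - p[1, ])^2))
  expect_equal(chord, 100, tolerance = 1e-3)
  expect_equal(sc$total_length_mm / chord, pi / 2, tolerance = 1e-4)

  # an s-curve with zero amplitude degenerates to the straight line
  s0 <- make_curve(phantom_spec("s_curve", length_mm = 100,
                                sine_amplitude_mm = 0))
  expect_equal(s0$total_length_mm, 100, tolerance = 1e-4)
  expect_equal(max(abs(s0$pos(seq(0, 100, 5))[, 1])), 0, tolerance = 1e-9)

  expect_error(make_curve(phantom_spec("straight", length_mm = 0)),
               "degenerate")
})

test_that("arc-length parameterization matches dense quadrature to <0.1%", {
  for (kind in c("semicircle", "s_curve", "full_aorta")) {
    spec <- phantom_spec(kind, sine_amplitude_mm = 10)
    cv <- make_curve(spec)
    ss <- seq(0, cv$total_length_mm, length.out = 4000)
    poly <- sum(sqrt(rowSums(diff(cv$pos(ss))^2)))
    expect_lt(abs(poly - cv$total_length_mm) / cv$total_length_mm, 1e-3)
    # unit-speed: consecutive samples ~1 mm apart at 1 mm arc steps
    d <- sqrt(rowSums(diff(cv$pos(seq(0, cv$total_length_mm, 1)))^2))
    expect_lt(max(abs(d - 1)), 0.02)
  }
})

test_that("rasterized phantom meets its constructed ground truth", {
  fx <- fx_full()
  ph <- fx$ph
  aorta <- structure_mask(ph$labels, "aorta")
  # masks nest correctly
  expect_true(all(aorta[ph$truth$lumen_mask]))
  expect_true(all(aorta[ph$truth$calc_mask]))
  expect_equal(sum(ph$truth$lumen_mask & ph$truth$calc_mask), 0)
  # every vocabulary structure present
  expect_length(ph$labels$missing, 0)
  # calcified fraction hits the 3% target
  expect_lt(abs(ph$truth$calc_fraction - 0.03), 0.005)
  # lumen HU model: mean within Monte-Carlo error of 300
  hu <- ph$image$voxels[ph$truth$lumen_mask]
  expect_gt(length(hu), 1e4)
  expect_lt(abs(mean(hu) - 300), 1)
  expect_lt(abs(sd(hu) - 20), 1)
  # landmark truths lie on the curve span in anatomical order
  lm <- ph$truth$landmarks_mm
  expect_true(all(lm >= 0 & lm <= ph$truth$total_length_mm))
  expect_true(lm[["renal"]] < lm[["diaphragm"]])
  expect_true(lm[["diaphragm"]] < lm[["subclavian"]] - 20)
  expect_true(lm[["subclavian"]] < lm[["brachiocephalic"]])
  expect_true(lm[["brachiocephalic"]] < lm[["ventricular_aortic"]])
  # analytic tortuosity: arc over chord, computed from the curve itself
  ti <- ph$truth$tortuosity$descending
  expect_equal(ti$index, ti$centerline_length_mm / ti$geometric_length_mm)
  expect_gte(ti$index, 1)
})

test_that("the generator is deterministic for a fixed seed", {
  a <- rasterize_phantom(phantom_spec("straight", length_mm = 30,
                                      spacing_mm = 1, calc_fraction = 0.02,
                                      seed = 21))
  b <- rasterize_phantom(phantom_spec("straight", length_mm = 30,
                                      spacing_mm = 1, calc_fraction = 0.02,
                                      seed = 21))
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$labels$voxels, b$labels$voxels)
  d <- rasterize_phantom(phantom_spec("straight", length_mm = 30,
                                      spacing_mm = 1, calc_fraction = 0.02,
                                      seed = 22))
  expect_false(identical(a$image$voxels, d$image$voxels))
})

test_that("cropping produces the expected restricted fields of view", {
  ca <- fx_cardiac()$ph
  lab <- connected_components(structure_mask(ca$labels, "aorta"))
  expect_gte(attr(lab, "n_components"), 2)
  ab <- fx_abdominal()$ph
  # no arch branches inside the abdominal crop
  expect_true("left_subclavian" %in% ab$labels$missing)
  expect_false("kidney_left" %in% ab$labels$missing)
})

test_that("phantom files round-trip through write_phantom", {
  ph <- rasterize_phantom(phantom_spec("straight", length_mm = 25,
                                       spacing_mm = 1, seed = 14))
  dir <- withr::local_tempdir()
  write_phantom(ph, dir, "case")
  expect_true(file.exists(file.path(dir, "case_image.nii.gz")))
  expect_true(file.exists(file.path(dir, "case_labels.nii.gz")))
  truth <- jsonlite::read_json(file.path(dir, "case_truth.json"))
  expect_equal(truth$total_length_mm, ph$truth$total_length_mm,
               tolerance = 1e-6)
})
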