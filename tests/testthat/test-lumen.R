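test_that("skeleton statistics recover the lumen HU model", {
  # constant-intensity tube: mu exact, sigma zero
  ph <- rasterize_phantom(phantom_spec("straight", length_mm = 60,
                                       spacing_mm = 1, seed = 31,
                                       hu = list(lumen_sd = 1e-9,
                                                 lumen_mean = 300)))
  aorta <- structure_mask(ph$labels, "aorta")
  st <- skeleton_lumen_stats(aorta, ph$image)
  expect_equal(st$mu_hu, 300, tolerance = 1e-6)
  expect_equal(st$sigma_hu, 0, tolerance = 1e-6)
  expect_true(all(aorta[st$skeleton])) # thinning is mask-internal

  # noisy phantom: skeleton samples agree with direct truth-mask statistics
  fx <- fx_full()
  st2 <- fx$lumen$stats
  hu_true <- fx$ph$image$voxels[fx$ph$truth$lumen_mask]
  expect_lt(abs(st2$mu_hu - mean(hu_true)), 3)
  expect_lt(abs(st2$sigma_hu - sd(hu_true)), 3)

  expect_error(skeleton_lumen_stats(aorta & FALSE, ph$image), "empty")
})

test_that("refined lumen overlaps truth and respects the HU band", {
  fx <- fx_full()
  lum <- fx$lumen$lumen_mask
  truth <- fx$ph$truth$lumen_mask
  expect_gte(dice(lum, truth), 0.95)
  # no ground-truth calcified voxel survives in the lumen
  expect_equal(sum(lum & fx$ph$truth$calc_mask), 0)
  # band property: violations only from morphological closing, and few
  band <- fx$lumen$band
  hu <- fx$ph$image$voxels
  viol <- sum(lum & !(hu >= band[1] & hu <= band[2]))
  expect_identical(viol, attr(lum, "n_band_violations"))
  expect_lt(viol / sum(lum), 0.02)

  # degenerate sigma = 0: band widened to +-1 HU, lumen ~ constant voxels
  ph0 <- rasterize_phantom(phantom_spec("straight", length_mm = 40,
                                        spacing_mm = 1, seed = 32,
                                        hu = list(lumen_sd = 1e-9)))
  a0 <- structure_mask(ph0$labels, "aorta")
  st0 <- skeleton_lumen_stats(a0, ph0$image)
  l0 <- refine_lumen(a0, ph0$image, st0)
  expect_gte(dice(l0, ph0$truth$lumen_mask), 0.9)
})

test_that("adaptive calcification threshold follows the printed formula", {
  expect_identical(calcification_threshold(300, 20, 3, 400), 400)
  expect_identical(calcification_threshold(300, 40, 3, 400), 420)
  expect_identical(calcification_threshold(100, 10, 1, 200), 200)
})

test_that("calcification extraction recovers the constructed fraction", {
  fx <- fx_full()
  expect_equal(fx$lumen$calc_threshold, 400,
               tolerance = 1e-9, ignore_attr = TRUE) # max(400, mu+3sigma<400)
  expect_lt(abs(fx$lumen$calcification_ratio -
                  100 * fx$ph$truth$calc_fraction), 1)
  # absence case: no calcification -> ratio zero, empty mask
  ph0 <- fx_const()$ph
  lr0 <- refine_aorta(structure_mask(ph0$labels, "aorta"), ph0$image)
  expect_equal(lr0$calcification_ratio, 0)
  expect_equal(sum(lr0$calcification_mask), 0)
})

test_that("raising alpha or min_hu never grows the calcification mask", {
  fx <- fx_full()
  aorta <- structure_mask(fx$ph$labels, "aorta")
  st <- fx$lumen$stats
  lum <- fx$lumen$lumen_mask
  prev <- NULL
  for (alpha in c(0, 1, 3, 5)) {
    cfg <- pipeline_config(alpha = alpha, min_hu = 300)
    cur <- extract_calcifications(aorta, lum, fx$ph$image, st,
                                  cfg)$calcification_mask
    if (!is.null(prev)) expect_true(all(prev[cur])) # cur subset of prev
    prev <- cur
  }
  prev <- NULL
  for (mh in c(300, 400, 600, 900)) {
    cfg <- pipeline_config(alpha = 3, min_hu = mh)
    cur <- extract_calcifications(aorta, lum, fx$ph$image, st,
                                  cfg)$calcification_mask
    if (!is.null(prev)) expect_true(all(prev[cur]))
    prev <- cur
  }
})

test_that("the parameter sweep reports ratios and failures per combination", {
  fx <- fx_full()
  case <- list(aorta_mask = structure_mask(fx$ph$labels, "aorta"),
               image = fx$ph$image)
  tab <- sweep_calcification_params(case, alphas = c(1, 3, 5), min_hus = 400)
  expect_equal(nrow(tab), 3)
  # ratio monotonically non-increasing in alpha at fixed min_hu
  expect_true(all(diff(tab$ratio_mean[order(tab$alpha)]) <= 1e-9))
  expect_true(all(tab$n_failed == 0))
  # single combination equals the direct extraction
  one <- sweep_calcification_params(case, alphas = 3, min_hus = 400)
  expect_equal(one$ratio_mean, fx$lumen$calcification_ratio, tolerance = 1e-9)

  # a degenerate segmentation (a few stray voxels instead of a vessel)
  # cannot be refined and is counted as a failed case
  bad_mask <- array(FALSE, dim(fx$ph$image$voxels))
  bad_mask[50:51, 50, 50] <- TRUE
  tab2 <- sweep_calcification_params(
    list(list(aorta_mask = bad_mask, image = fx$ph$image)),
    alphas = 1, min_hus = 200)
  expect_gt(tab2$n_failed, 0)

  # a low-contrast phantom with a strong radial HU gradient: the skeleton
  # samples the darker core, so much of the bright rim falls above the
  # band and is reassigned to the calcification compartment
  bad <- rasterize_phantom(phantom_spec("straight", length_mm = 60,
                                        spacing_mm = 1, seed = 33,
                                        hu = list(lumen_mean = 200,
                                                  lumen_sd = 5,
                                                  lumen_gradient_hu_mm = 60)))
  tab3 <- sweep_calcification_params(
    list(list(aorta_mask = structure_mask(bad$labels, "aorta"),
              image = bad$image)),
    alphas = 1, min_hus = 200)
  expect_gt(tab3$ratio_mean, 10)
})
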