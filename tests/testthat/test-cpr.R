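cpr_cfg <- pipeline_config(cpr_halfwidth_mm = 20)

test_that("straightening reproduces cross-sections of an axis-aligned tube", {
  fx <- fx_straight()
  st <- straighten(fx$ph$image, fx$lumen$lumen_mask, fx$centerline, cpr_cfg)
  # slice count formula
  expect_equal(dim(st$lumen_slices)[3],
               floor(fx$centerline$total_length_mm /
                       cpr_cfg$cpr_slice_step_mm) + 1)
  # per-slice comparison against the original z-slices of the lumen
  m <- dim(st$lumen_slices)[1]
  c0 <- (m + 1) / 2
  res <- st$inplane_res_mm
  vol <- fx$ph$image
  dices <- vapply(seq(10, dim(st$lumen_slices)[3] - 10, by = 10),
                  function(i) {
    z <- st$centers[i, 3]
    k <- round((z - vol$origin[3]) / vol$spacing[3]) + 1
    orig <- fx$lumen$lumen_mask[, , k]
    # project the original lumen voxels of this z-slice into slice coords
    px <- which(orig, arr.ind = TRUE)
    dx <- vol$origin[1] + (px[, 1] - 1) * vol$spacing[1] - st$centers[i, 1]
    dy <- vol$origin[2] + (px[, 2] - 1) * vol$spacing[2] - st$centers[i, 2]
    dz <- (z - st$centers[i, 3])
    nrm <- st$frames$normal[i, ]
    bin <- st$frames$binormal[i, ]
    iu <- round((dx * nrm[1] + dy * nrm[2] + dz * nrm[3]) / res + c0)
    iv <- round((dx * bin[1] + dy * bin[2] + dz * bin[3]) / res + c0)
    ok <- iu >= 1 & iu <= m & iv >= 1 & iv <= m
    hits <- st$lumen_slices[, , i][cbind(iu[ok], iv[ok])]
    mean(hits)
  }, numeric(1))
  expect_gt(min(dices), 0.95)
})

test_that("cross-sectional areas match the analytic circle", {
  # resample the ground-truth lumen along the measured centerline: this
  # isolates the reformatting itself from segmentation bias
  fx <- fx_straight_cpr()
  st <- straighten(fx$ph$image, fx$ph$truth$lumen_mask, fx$centerline,
                   cpr_cfg)
  prof <- csa_profile(st)
  interior <- prof$arc_length_mm > 10 &
    prof$arc_length_mm < fx$centerline$total_length_mm - 10
  areas <- prof$area_mm2[interior]
  expect_lt(max(abs(areas - pi * 100)) / (pi * 100), 0.04)
  expect_lt(mean(abs(areas - pi * 100)) / (pi * 100), 0.02)
  # constant-radius tube: coefficient of variation < 3%
  expect_lt(sd(areas) / mean(areas), 0.03)
  # volume conservation within 5% on a low-curvature phantom
  vol_cpr <- sum(prof$area_mm2) * st$slice_step_mm
  vol_vox <- sum(fx$ph$truth$lumen_mask) * prod(fx$ph$image$spacing)
  expect_lt(abs(vol_cpr - vol_vox) / vol_vox, 0.05)
})

test_that("profile flags empty slices and localizes an aneurysm bump", {
  # slice beyond the lumen end: area 0, flagged invalid
  fx <- fx_straight()
  cl <- fx$centerline
  long <- cl
  long$samples <- rbind(cl$samples, cl$samples[nrow(cl$samples), ] +
                          c(0, 0, 30))
  long <- aortax:::resample_polyline(long$samples, 1)
  long <- compute_frames(long)
  st <- straighten(fx$ph$image, fx$lumen$lumen_mask, long, cpr_cfg)
  prof <- csa_profile(st)
  expect_true(any(!prof$valid))
  expect_equal(prof$area_mm2[!prof$valid], rep(0, sum(!prof$valid)))

  an <- fx_aneurysm()
  expect_false(is.null(an$report$csa))
  i <- which.max(an$report$csa$area_mm2)
  # the profile maximum sits at the constructed bump center (s = 20)
  bump_world <- an$ph$truth$curve$pos(20)
  meas <- an$report$measurements
  inf_row <- meas[meas$name == "infrarenal", ]
  expect_lt(abs(inf_row$arc_length_mm - an$report$csa$arc_length_mm[i]), 3)
})

test_that("straightened lumen pixels map back inside the vessel", {
  fx <- fx_semicircle()
  st <- straighten(fx$ph$image, fx$lumen$lumen_mask, fx$centerline, cpr_cfg)
  m <- dim(st$lumen_slices)[1]
  c0 <- (m + 1) / 2
  res <- st$inplane_res_mm
  dil <- dilate_mask(fx$lumen$lumen_mask, 2, fx$ph$image$spacing)
  dil_num <- array(as.numeric(dil), dim(dil))
  inside <- c()
  for (i in seq(5, dim(st$lumen_slices)[3] - 5, by = 7)) {
    px <- which(st$lumen_slices[, , i], arr.ind = TRUE)
    if (!nrow(px)) next
    u <- (px[, 1] - c0) * res
    v <- (px[, 2] - c0) * res
    pts <- cbind(st$centers[i, 1] + u * st$frames$normal[i, 1] +
                   v * st$frames$binormal[i, 1],
                 st$centers[i, 2] + u * st$frames$normal[i, 2] +
                   v * st$frames$binormal[i, 2],
                 st$centers[i, 3] + u * st$frames$normal[i, 3] +
                   v * st$frames$binormal[i, 3])
    val <- aortax:::cpp_sample_volume(dil_num, dim(dil), fx$ph$image$spacing,
                                      fx$ph$image$origin, pts, 0, TRUE)
    inside <- c(inside, val >= 0.5)
  }
  expect_gte(mean(inside), 0.99)
})
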