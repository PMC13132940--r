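test_that("endpoint rules fire per scan class", {
  fx <- fx_full()
  eps <- determine_endpoints(fx$lumen$lumen_mask, fx$ph$labels, "full",
                             fx$ph$image)
  expect_length(eps, 1)
  # start near the constructed bifurcation (arc 0), end near the valve
  cv <- fx$ph$truth$curve
  expect_lt(truth_arc_of(cv, eps[[1]]$start), 20)
  expect_gt(truth_arc_of(cv, eps[[1]]$end), cv$total_length_mm - 20)

  ab <- fx_abdominal()
  lr <- refine_aorta(structure_mask(ab$ph$labels, "aorta"), ab$ph$image)
  eab <- determine_endpoints(lr$lumen_mask, ab$ph$labels, "abdominal",
                             ab$ph$image)
  # end point sits on the topmost occupied slice of the cropped lumen
  ztop <- max(which(apply(lr$lumen_mask, 3, any)))
  zend <- ab$ph$image$origin[3] + (ztop - 1) * ab$ph$image$spacing[3]
  expect_lt(abs(eab[[1]]$end[3] - zend), 1e-6)

  ca <- fx_cardiac()
  lrc <- refine_aorta(structure_mask(ca$ph$labels, "aorta"), ca$ph$image)
  eca <- determine_endpoints(lrc$lumen_mask, ca$ph$labels, "cardiac_two_part",
                             ca$ph$image)
  expect_length(eca, 2)
  expect_setequal(vapply(eca, `[[`, "", "name"),
                  c("ascending", "descending"))
})

test_that("the medial path stays central in constant-radius tubes", {
  for (fx in list(fx_straight(), fx_semicircle())) {
    n <- nrow(fx$ph$truth$centerline)
    ep <- list(start = fx$ph$truth$centerline[1, 1:3],
               end = fx$ph$truth$centerline[n, 1:3])
    raw <- extract_centerline(fx$lumen$lumen_mask, ep, fx$ph$image)
    # interior medialness (near the flat end caps the distance to the
    # boundary is capped by the cap itself, whatever the centering)
    arc <- c(0, cumsum(sqrt(rowSums(diff(raw)^2))))
    interior <- arc > 12 & arc < max(arc) - 12
    expect_gte(mean(attr(raw, "dtb")[interior]), 0.8 * 10)
    # every path point within one voxel of the analytic axis
    if (fx$ph$truth$spec$curve_kind == "straight")
      expect_lt(max(sqrt(raw[, 1]^2 + raw[, 2]^2)), 2 * 0.8)
  }
  # semicircle path length within 3% of pi * R
  sc <- fx_semicircle()
  expect_lt(abs(sc$centerline$total_length_mm - pi * 50) / (pi * 50), 0.03)
})

test_that("spline fitting is accurate, monotone and idempotent", {
  # noisy straight path with +-0.5 mm jitter: tangents within 2 degrees
  set.seed(41)
  z <- seq(0, 100, by = 0.8)
  raw <- cbind(runif(length(z), -0.5, 0.5), runif(length(z), -0.5, 0.5), z)
  # cross-validated smoothness, the mode the pipeline uses once path noise
  # is uncorrelated
  cl <- fit_smoothing_spline(raw, step_mm = 1, df_per_mm = NULL)
  ang <- acos(pmin(1, abs(cl$tangents[, 3]))) * 180 / pi
  expect_lt(max(ang), 2)
  # parameterization identity
  expect_true(all(diff(cl$arc_length) > 0))
  expect_equal(cl$arc_length[length(cl$arc_length)], cl$total_length_mm)
  # residual contract on a real phantom path
  sc <- fx_semicircle()
  n <- nrow(sc$ph$truth$centerline)
  ep <- list(start = sc$ph$truth$centerline[1, 1:3],
             end = sc$ph$truth$centerline[n, 1:3])
  raw2 <- extract_centerline(sc$lumen$lumen_mask, ep, sc$ph$image)
  cl2 <- fit_smoothing_spline(raw2, step_mm = 1)
  pred <- cl2$samples[vapply(seq_len(nrow(raw2)), function(i) {
    which.min(colSums((t(cl2$samples) - raw2[i, ])^2))
  }, integer(1)), ]
  expect_lt(sqrt(mean(rowSums((pred - raw2)^2))), 2)
  # discrete curvature of the fitted semicircle ~ 1/R within 10%
  # (finite difference over a +-5 mm window, the scale at which curvature
  # is meaningful on a voxel-derived curve)
  cl3 <- sc$centerline
  nn <- nrow(cl3$tangents)
  h <- 5
  dT <- (cl3$tangents[(1 + 2 * h):nn, ] - cl3$tangents[1:(nn - 2 * h), ]) /
    (cl3$arc_length[(1 + 2 * h):nn] - cl3$arc_length[1:(nn - 2 * h)])
  curv <- sqrt(rowSums(dT^2))
  interior <- seq(10, length(curv) - 10)
  expect_lt(abs(median(curv[interior]) - 1 / 50) / (1 / 50), 0.1)
  # idempotence: refitting the resampled centerline barely moves it
  refit <- fit_smoothing_spline(cl3$samples, step_mm = 1, df_per_mm = NULL)
  k <- min(nrow(refit$samples), nrow(cl3$samples))
  expect_lt(sqrt(mean(rowSums((refit$samples[1:k, ] -
                                 cl3$samples[1:k, ])^2))), 0.1)
  expect_error(fit_smoothing_spline(raw[1:3, ]), "too few")
})

test_that("frames are orthonormal, continuous and flip-corrected", {
  for (fx in list(fx_straight(), fx_scurve(), fx_semicircle())) {
    cl <- fx$centerline
    tg <- cl$tangents
    no <- cl$frames$normal
    bi <- cl$frames$binormal
    # orthonormal to 1e-6
    expect_lt(max(abs(rowSums(tg * no))), 1e-6)
    expect_lt(max(abs(rowSums(tg * bi))), 1e-6)
    expect_lt(max(abs(rowSums(no * bi))), 1e-6)
    expect_lt(max(abs(rowSums(no^2) - 1)), 1e-6)
    # flip rule: no consecutive normal reversal anywhere (brute force),
    # including across the s-curve inflections
    dots <- rowSums(no[-nrow(no), ] * no[-1, ])
    expect_true(all(dots >= 0))
    # continuity: consecutive normals within 15 degrees at 1 mm steps
    expect_lt(max(acos(pmin(1, dots))) * 180 / pi, 15)
  }
  # exact straight line: all frames identical (zero curvature)
  line <- aortax:::resample_polyline(cbind(0, 0, seq(0, 50, 5)), 1)
  line <- compute_frames(line)
  expect_lt(max(abs(sweep(line$frames$normal, 2,
                          line$frames$normal[1, ]))), 1e-9)
  # up-vector parallel to the tangent falls back to the lateral axis
  fb <- compute_frames(line, up_vector = c(0, 0, 2))
  expect_lt(max(abs(rowSums(fb$frames$normal * fb$tangents))), 1e-9)
})

test_that("tube centerlines recover analytic tortuosity", {
  st <- fx_straight()
  ti <- tortuosity(st$centerline, 0, st$centerline$total_length_mm)
  expect_lt(abs(ti$index - 1), 0.001)
  sc <- fx_semicircle()
  ti2 <- tortuosity(sc$centerline, 0, sc$centerline$total_length_mm)
  expect_lt(abs(ti2$index - pi / 2), 0.01)
})
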