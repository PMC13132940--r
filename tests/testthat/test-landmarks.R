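test_that("overlap landmarks are the exact arg-min over samples", {
  fx <- fx_full()
  rep <- fx$report
  cl_len <- attr(rep$csa, "line_length")
  lum <- fx$lumen$lumen_mask
  labs <- fx$ph$labels
  cl <- fx$cl
  lv <- structure_mask(labs, "lv_blood")
  lm <- overlap_landmark(lum, lv, cl, fx$ph$image, 5, "ventricular_aortic")
  expect_false(lm$missing)
  # brute force: recompute the overlap COM and exhaustively search samples
  ov <- dilate_mask(lv, 5, fx$ph$image$spacing) &
    dilate_mask(lum, 5, fx$ph$image$spacing)
  com <- colMeans(aortax:::linear_to_world(fx$ph$image, which(ov)))
  d2 <- rowSums(sweep(cl$samples, 2, com)^2)
  expect_equal(lm$arc_length_mm, cl$arc_length[which.min(d2)])

  # an organ too far from the lumen leaves the landmark missing
  far <- array(FALSE, dim(lum))
  far[1:4, 1:4, 1:4] <- TRUE
  lm2 <- overlap_landmark(lum, far, cl, fx$ph$image, 5, "probe")
  expect_true(lm2$missing)
  # empty organ label
  lm3 <- overlap_landmark(lum, far & FALSE, cl, fx$ph$image, 5, "probe")
  expect_true(lm3$missing)
})

test_that("renal landmark projects the kidney line onto the centerline", {
  fx <- fx_full()
  labs <- fx$ph$labels
  cl <- fx$cl
  kl <- structure_mask(labs, "kidney_left")
  kr <- structure_mask(labs, "kidney_right")
  lm <- renal_landmark(kl, kr, cl, fx$ph$image)
  # brute-force point-to-line distance over all samples confirms the argmin
  c1 <- colMeans(aortax:::linear_to_world(fx$ph$image, which(kl)))
  c2 <- colMeans(aortax:::linear_to_world(fx$ph$image, which(kr)))
  u <- (c2 - c1) / sqrt(sum((c2 - c1)^2))
  rel <- sweep(cl$samples, 2, c1)
  t <- rel %*% u
  d2 <- rowSums((rel - t %*% t(u))^2)
  expect_equal(lm$arc_length_mm, cl$arc_length[which.min(d2)])
  # degenerate kidney line
  expect_error(renal_landmark(kl, kl, cl, fx$ph$image), "degenerate")
  # missing kidney -> landmark missing with warning text
  lm2 <- renal_landmark(kl, kl & FALSE, cl, fx$ph$image)
  expect_true(lm2$missing)
})

test_that("diaphragm landmark converges to the RV-liver midpoint", {
  fx <- fx_full()
  labs <- fx$ph$labels
  cl <- fx$cl
  lm <- diaphragm_landmark(structure_mask(labs, "rv_blood"),
                           structure_mask(labs, "liver"), cl, fx$ph$image)
  expect_false(lm$missing)
  # midpoint equidistant from the converged pair (within half a voxel)
  p <- lm$pair
  expect_lt(abs(sqrt(sum((p$midpoint - p$rv)^2)) -
                  sqrt(sum((p$midpoint - p$liver)^2))), 0.5)
  # the constructed diaphragm plane sits at the abdominal/thoracic junction
  err <- landmark_arc_error(fx$report, fx$ph$truth$curve, "diaphragm",
                            fx$ph$truth$landmarks_mm[["diaphragm"]])
  expect_lt(err, 10)
  lm2 <- diaphragm_landmark(structure_mask(labs, "rv_blood") & FALSE,
                            structure_mask(labs, "liver"), cl, fx$ph$image)
  expect_true(lm2$missing)
})

test_that("arch landmarks respect the 2 cm distal offset and ordering", {
  fx <- fx_full()
  lms <- fx$report$landmarks
  arc_of <- function(nm) lms$arc_length_mm[lms$name == nm]
  # distal arch exactly 20 mm distal (toward the bifurcation) of the
  # subclavian projection, up to the 1 mm sampling of the centerline
  expect_lt(abs((arc_of("left_subclavian") - arc_of("distal_arch")) - 20), 1)
  # anatomical ordering along the centerline
  expect_true(arc_of("distal_arch") < arc_of("proximal_arch"))
  expect_true(arc_of("proximal_arch") < arc_of("ventricular_aortic"))
  expect_true(arc_of("left_subclavian") < arc_of("left_common_carotid"))
  expect_true(arc_of("left_common_carotid") < arc_of("proximal_arch"))
})

test_that("root landmark windows follow the protocol", {
  fx <- fx_full()
  lms <- fx$report$landmarks
  arc_of <- function(nm) lms$arc_length_mm[lms$name == nm]
  va <- arc_of("ventricular_aortic")
  sv <- arc_of("sinus_valsalva")
  stj <- arc_of("sinotubular_junction")
  # sinus within 20 mm distal of the junction (half-open window)
  expect_true(sv < va && sv >= va - 20)
  # sinotubular junction 5-25 mm beyond the sinus
  expect_true(stj <= sv - 5 && stj >= sv - 25)
  # annulus within 10 mm proximal of the junction
  expect_true(arc_of("annulus") >= va - 1 && arc_of("annulus") <= va + 10 + 1)
})

test_that("segments are contiguous, cover the span, and degrade explicitly", {
  fx <- fx_full()
  segs <- fx$report$segments
  expect_equal(nrow(segs), 5)
  expect_true(all(segs$available))
  o <- order(segs$start_mm)
  expect_equal(segs$start_mm[o][-1], segs$end_mm[o][-5]) # contiguous, exact
  expect_equal(segs$start_mm[o][1], 0)
  lms <- fx$report$landmarks
  va <- lms$arc_length_mm[lms$name == "ventricular_aortic"]
  expect_equal(max(segs$end_mm), va) # covers [0, ventricular-aortic]

  # removing the renal landmark leaves both abdominal segments unavailable
  cl <- fx$cl
  lm_list <- list(
    ventricular_aortic = aortax:::new_landmark("ventricular_aortic", 350,
                                               cl$samples[1, ]),
    proximal_arch = aortax:::new_landmark("proximal_arch", 270, cl$samples[1, ]),
    distal_arch = aortax:::new_landmark("distal_arch", 205, cl$samples[1, ]),
    diaphragm = aortax:::new_landmark("diaphragm", 100, cl$samples[1, ]),
    renal = aortax:::new_landmark("renal", missing = TRUE, warning = "gone"))
  segs2 <- partition_segments(lm_list, cl, "full")
  expect_false(segs2$available[segs2$segment == "infrarenal"])
  expect_false(segs2$available[segs2$segment == "suprarenal"])
  expect_true(segs2$available[segs2$segment == "descending"])

  # abdominal crop: only the abdominal segments (plus a descending stub)
  ab <- fx_abdominal()
  expect_true(all(ab$report$segments$segment %in%
                    c("infrarenal", "suprarenal", "descending")))
})

test_that("landmark world points equal the centerline samples at their arcs", {
  fx <- fx_full()
  lms <- fx$report$landmarks
  csa <- fx$report$csa
  present <- lms[!lms$missing & lms$name != "annulus", ]
  # all reported arcs within the analyzed span
  expect_true(all(present$arc_length_mm >= 0 &
                    present$arc_length_mm <= attr(csa, "line_length") + 1))
})
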