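test_that("max-chord diameter matches analytic shapes", {
  # digitized disk, radius 10 mm at 0.5 mm pixels
  d <- max_diameter(disk_mask(20), 0.5)
  expect_lt(abs(d$max_diameter_mm - 20), 0.5)
  expect_false(d$degenerate)

  # digitized ellipse 15/10 mm semi-axes: compare against a brute-force
  # search over boundary pixel pairs whose segment passes through the COM
  el <- ellipse_mask(30, 20)
  d2 <- max_diameter(el, 0.5)
  expect_lt(abs(d2$max_diameter_mm - 30), 0.5)
  px <- which(el & !(el[c(1, 1:(nrow(el) - 1)), ] &
                       el[c(2:nrow(el), nrow(el)), ] &
                       el[, c(1, 1:(ncol(el) - 1))] &
                       el[, c(2:ncol(el), ncol(el))]), arr.ind = TRUE)
  com <- colMeans(which(el, arr.ind = TRUE))
  best <- 0
  for (i in seq_len(nrow(px))) {
    p <- px[i, ]
    rest <- px[-i, , drop = FALSE]
    # distance from COM to the segment p-q, vectorized over q
    vx <- rest[, 1] - p[1]; vy <- rest[, 2] - p[2]
    tt <- pmin(pmax(((com[1] - p[1]) * vx + (com[2] - p[2]) * vy) /
                      pmax(vx^2 + vy^2, 1e-9), 0), 1)
    dd <- sqrt((p[1] + tt * vx - com[1])^2 + (p[2] + tt * vy - com[2])^2)
    thru <- dd < 1
    if (any(thru))
      best <- max(best, sqrt(max(vx[thru]^2 + vy[thru]^2)))
  }
  expect_lt(abs(d2$max_diameter_mm - best * 0.5), 0.75)

  # single-pixel mask flagged degenerate
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  d3 <- max_diameter(one, 0.5)
  expect_true(d3$degenerate)
  # crescent: COM outside the mask
  cres <- disk_mask(20) & !disk_mask(18, n = 49)
  cres[, 1:25] <- FALSE
  expect_warning(d4 <- max_diameter(cres, 0.5), "COM")
  expect_true(d4$degenerate)
  expect_error(max_diameter(one & FALSE, 0.5), "empty")
})

test_that("max chord is at least the equivalent-circle diameter", {
  fx <- fx_full()
  m <- fx$report$measurements
  eq <- 2 * sqrt(m$csa_mm2 / pi)
  expect_true(all(m$max_diameter_mm >= eq - 0.6)) # grid tolerance
})

test_that("ellipse aspect QC distinguishes disks from bars", {
  a <- ellipse_aspect_check(disk_mask(20), 2.5)
  expect_lt(abs(a$aspect_ratio - 1), 0.05)
  expect_true(a$pass)
  bar <- matrix(FALSE, 50, 50); bar[6:45, 21:30] <- TRUE # 40 x 10 bar
  b <- ellipse_aspect_check(bar, 2.5)
  # brute-force second moments agree
  px <- which(bar, arr.ind = TRUE)
  ev <- eigen(cov(px), only.values = TRUE)$values
  expect_equal(b$aspect_ratio, sqrt(ev[1] / ev[2]), tolerance = 1e-9)
  expect_lt(abs(b$aspect_ratio - 4), 0.15)
  expect_false(b$pass)
  # boundary rule: ratio exactly at the threshold passes
  c <- ellipse_aspect_check(bar, b$aspect_ratio)
  expect_true(c$pass)
})

test_that("tortuosity is arc over chord and never below one", {
  st <- fx_straight()
  expect_lt(abs(tortuosity(st$centerline, 0,
                           st$centerline$total_length_mm)$index - 1), 0.001)
  sc <- fx_semicircle()
  ti <- tortuosity(sc$centerline, 0, sc$centerline$total_length_mm)
  expect_lt(abs(ti$index - pi / 2), 0.01)
  expect_equal(ti$index, ti$centerline_length_mm / ti$geometric_length_mm)
  expect_error(tortuosity(st$centerline, 10, 10), "coincident")
  # arc >= chord across tortuous phantoms
  for (seed in 1:5) {
    ph <- rasterize_phantom(phantom_spec("s_curve", length_mm = 80,
                                         sine_amplitude_mm = 8,
                                         spacing_mm = 1, seed = seed))
    tc <- tube_centerline(ph)
    expect_gte(tortuosity(tc$centerline, 0,
                          tc$centerline$total_length_mm)$index, 1 - 1e-6)
  }
})

test_that("agreement metrics reproduce hand-computed values exactly", {
  m <- c(18.2, 21.5, 24.9, 27.3, 30.1, 33.4, 36.0, 22.8, 26.7, 29.5)
  a <- c(19.0, 21.1, 25.6, 27.0, 31.2, 33.9, 35.2, 23.5, 26.4, 30.6)
  s <- agreement_metrics(a, m)
  expect_equal(s$n, 10)
  expect_equal(s$mae, 0.67, tolerance = 1e-9)
  expect_equal(s$mape_percent, 2.54625133543208, tolerance = 1e-9)
  expect_equal(s$bias, 0.31, tolerance = 1e-9)
  expect_equal(s$pearson_r, 0.991981567152631, tolerance = 1e-9)
  expect_equal(s$cv_percent, 1.24724262733558, tolerance = 1e-9)
  expect_equal(s$loa_low, -1.04619788788772, tolerance = 1e-9)
  expect_equal(s$loa_high, 1.66619788788772, tolerance = 1e-9)
  expect_equal(s$out_of_loa_fraction, 0)
  expect_gte(s$mae, abs(s$bias))

  # identity and perfect-correlation edge cases
  id <- agreement_metrics(m, m)
  expect_equal(id$mae, 0)
  expect_equal(id$bias, 0)
  expect_equal(id$cv_percent, 0)
  expect_equal(id$out_of_loa_fraction, 0)
  expect_equal(agreement_metrics(2 * m, m)$pearson_r, 1, tolerance = 1e-12)
  # spec'd small example: mae 2, bias 4/3
  sm <- agreement_metrics(c(12, 19, 33), c(10, 20, 30))
  expect_equal(sm$mae, 2, tolerance = 1e-12)
  expect_equal(sm$bias, 4 / 3, tolerance = 1e-12)

  expect_error(agreement_metrics(1, 1), "at least 2")
  expect_error(agreement_metrics(c(1, 2), c(0, 2)), "positive")
  # absolute-value CV variant is never negative
  expect_gte(agreement_metrics(a, m, cv_absolute = TRUE)$cv_percent, 0)
})
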