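# Shared fixtures: phantoms and their analyses are expensive, so they are
# built lazily once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# centerline through a bare tube phantom, anchored at the analytic ends
tube_centerline <- function(ph, config = pipeline_config()) {
  lr <- refine_aorta(structure_mask(ph$labels, "aorta"), ph$image, config)
  n <- nrow(ph$truth$centerline)
  ep <- list(start = ph$truth$centerline[1, 1:3],
             end = ph$truth$centerline[n, 1:3])
  list(lumen = lr, centerline = centerline_pipeline(lr$lumen_mask, ep,
                                                    ph$image, config))
}

fx_straight <- function() fixture("straight", function() {
  ph <- rasterize_phantom(phantom_spec("straight", length_mm = 100,
                                       spacing_mm = 0.8, seed = 2))
  c(list(ph = ph), tube_centerline(ph))
})

fx_semicircle <- function() fixture("semicircle", function() {
  ph <- rasterize_phantom(phantom_spec("semicircle", arch_radius_mm = 50,
                                       spacing_mm = 0.8, seed = 3))
  c(list(ph = ph), tube_centerline(ph))
})

# straight tube at the generator's default 1 mm resolution (used by the
# reformatting conservation checks)
fx_straight_cpr <- function() fixture("straight_cpr", function() {
  ph <- rasterize_phantom(phantom_spec("straight", length_mm = 100,
                                       spacing_mm = 1, seed = 7))
  c(list(ph = ph), tube_centerline(ph))
})

fx_scurve <- function() fixture("scurve", function() {
  ph <- rasterize_phantom(phantom_spec("s_curve", length_mm = 100,
                                       sine_amplitude_mm = 15,
                                       spacing_mm = 1, seed = 4))
  c(list(ph = ph), tube_centerline(ph))
})

# full aorta with default conditions (lumen N(300, 20), wall 50 HU,
# calcifications at 3% target fraction)
fx_full <- function() fixture("full", function() {
  ph <- full_aorta_phantom(seed = 1, calc_fraction = 0.03)
  lumen <- refine_aorta(structure_mask(ph$labels, "aorta"), ph$image)
  eps <- determine_endpoints(lumen$lumen_mask, ph$labels, "full", ph$image)
  cl <- centerline_pipeline(lumen$lumen_mask, eps[[1]], ph$image)
  # keep the cache lean: drop mask-sized members the tests do not touch
  lumen$thresholded_mask <- NULL
  lumen$stats$sample_mask <- NULL
  lumen$stats$skeleton <- NULL
  list(ph = ph, lumen = lumen, endpoints = eps, cl = cl,
       report = analyze(ph$image, ph$labels))
})

# constant-radius variant (no root features) for diameter recovery
fx_const <- function() fixture("const", function() {
  ph <- full_aorta_phantom(seed = 2, root_features = FALSE)
  list(ph = ph, report = analyze(ph$image, ph$labels))
})

fx_aneurysm <- function() fixture("aneurysm", function() {
  ph <- full_aorta_phantom(seed = 6, root_features = FALSE,
                           aneurysm = list(center_mm = 20, amplitude_mm = 8,
                                           width_mm = 6))
  list(ph = ph, report = analyze(ph$image, ph$labels))
})

fx_cardiac <- function() fixture("cardiac", function() {
  ph <- cardiac_phantom(seed = 5)
  list(ph = ph, report = analyze(ph$image, ph$labels))
})

fx_abdominal <- function() fixture("abdominal", function() {
  ph <- abdominal_phantom(seed = 5)
  list(ph = ph, report = analyze(ph$image, ph$labels))
})

fx_noncontrast <- function() fixture("noncontrast", function() {
  ph <- noncontrast_phantom(seed = 4)
  list(ph = ph, report = analyze(ph$image, ph$labels))
})

# arc-length of the point on the truth curve nearest to a world point;
# landmark errors are evaluated this way so they are invariant to where the
# measured centerline happens to start
truth_arc_of <- function(curve, point) {
  ss <- seq(0, curve$total_length_mm, by = 0.25)
  p <- curve$pos(ss)
  ss[which.min((p[, 1] - point[1])^2 + (p[, 2] - point[2])^2 +
                 (p[, 3] - point[3])^2)]
}

landmark_arc_error <- function(report, curve, name, truth_s) {
  lm <- report$landmarks[report$landmarks$name == name, ]
  if (nrow(lm) != 1 || lm$missing) return(Inf)
  abs(truth_arc_of(curve, c(lm$x_mm, lm$y_mm, lm$z_mm)) - truth_s)
}

# digitized disk / ellipse / bar cross-section masks (pixel grid)
disk_mask <- function(radius_px, n = 2 * radius_px + 9) {
  c0 <- (n + 1) / 2
  x <- matrix(rep(1:n, n), n)
  y <- t(x)
  (x - c0)^2 + (y - c0)^2 <= radius_px^2
}

ellipse_mask <- function(a_px, b_px, n = 2 * a_px + 9) {
  c0 <- (n + 1) / 2
  x <- matrix(rep(1:n, n), n)
  y <- t(x)
  ((x - c0) / a_px)^2 + ((y - c0) / b_px)^2 <= 1
}

sphere_mask <- function(radius_mm, spacing = 1) {
  n <- ceiling(2 * radius_mm / spacing) + 9
  c0 <- (n + 1) / 2
  ax <- (1:n - c0) * spacing
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  X^2 + Y^2 + Z^2 <= radius_mm^2
}
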