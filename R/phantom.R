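# Synthetic CTA phantoms with analytic ground truth. The generator emulates
# the inputs the pipeline sees in practice: a contrast-enhanced lumen
# (approximately normal HU, mean 300, sd 20), a darker aortic wall ring,
# bright calcified plaques at the lumen/wall interface, surrounding organ
# blobs used by the landmark rules, and a known centerline geometry so every
# downstream quantity has a constructed truth.

#' Phantom specification
#'
#' @param curve_kind one of `"straight"`, `"semicircle"`, `"s_curve"`,
#'   `"full_aorta"`.
#' @param length_mm tube length for straight/s-curve phantoms.
#' @param arch_radius_mm circle radius for the semicircle and for the aortic
#'   arch of the full phantom.
#' @param abdominal_mm,thoracic_mm,ascending_mm lengths of the three straight
#'   runs of the full-aorta curve (bifurcation to diaphragm, diaphragm to
#'   arch, arch to valve).
#' @param sine_amplitude_mm,sine_periods lateral sinusoidal tortuosity of the
#'   descending run (smoothly windowed so curve junctions stay C1).
#' @param lumen_radius_mm base lumen radius.
#' @param wall_thickness_mm aortic wall ring thickness.
#' @param aneurysm optional `list(center_mm=, amplitude_mm=, width_mm=)`
#'   Gaussian radius bump.
#' @param root_features add sinus-of-Valsalva bulge and sinotubular narrowing
#'   near the valve end (full aorta only).
#' @param hu named list overriding the HU model (means/sds for lumen, wall,
#'   background, calcification, organs). `sp_fraction`/`sp_amplitude` inject
#'   salt-and-pepper outliers into the peripheral half of the aortic cross
#'   section, emulating the partial-volume and streak artifacts that make
#'   unenhanced vessel boundaries ragged while the vessel core stays
#'   representative.
#' @param calc_fraction target calcified voxel fraction of the aorta,
#'   `|calc| / (|lumen| + |calc|)`, in `[0, 0.5]`.
#' @param calc_blob_radius_mm radius of individual calcification blobs.
#' @param organs logical: rasterize the organ layout (full aorta only).
#' @param spacing_mm voxel spacing (isotropic scalar or length 3).
#' @param margin_mm padding added around all structures.
#' @param seed integer RNG seed; a fixed seed gives byte-identical phantoms.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(curve_kind = c("full_aorta", "straight", "semicircle",
                                        "s_curve"),
                         length_mm = 100,
                         arch_radius_mm = if (match.arg(curve_kind) == "semicircle") 50 else 30,
                         abdominal_mm = 100, thoracic_mm = 100,
                         ascending_mm = 60,
                         sine_amplitude_mm = if (match.arg(curve_kind) == "s_curve") 15 else 0,
                         sine_periods = 1,
                         lumen_radius_mm = 10,
                         wall_thickness_mm = 2,
                         aneurysm = NULL,
                         root_features = match.arg(curve_kind) == "full_aorta",
                         hu = list(),
                         calc_fraction = 0,
                         calc_blob_radius_mm = 2.5,
                         organs = match.arg(curve_kind) == "full_aorta",
                         spacing_mm = 1,
                         margin_mm = 6,
                         seed = 1L) {
  curve_kind <- match.arg(curve_kind)
  if (lumen_radius_mm <= wall_thickness_mm || wall_thickness_mm < 0)
    stop("need lumen radius > wall thickness >= 0")
  if (calc_fraction < 0 || calc_fraction > 0.5)
    stop("calc_fraction must be in [0, 0.5]")
  hu_model <- utils::modifyList(list(
    lumen_mean = 300, lumen_sd = 20,
    wall_mean = 50, wall_sd = 15,
    background_mean = 40, background_sd = 15,
    calc_mean = 800, calc_sd = 30,
    organ_means = c(lv_blood = 280, rv_blood = 200, liver = 90,
                    kidney_left = 120, kidney_right = 120,
                    brachiocephalic_trunk = 280, left_common_carotid = 280,
                    left_subclavian = 280, iliac_left = 280, iliac_right = 280),
    organ_sd = 20,
    lumen_gradient_hu_mm = 0,
    sp_fraction = 0, sp_amplitude = 500), hu)
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3)
  structure(list(curve_kind = curve_kind, length_mm = length_mm,
                 arch_radius_mm = arch_radius_mm,
                 abdominal_mm = abdominal_mm, thoracic_mm = thoracic_mm,
                 ascending_mm = ascending_mm,
                 sine_amplitude_mm = sine_amplitude_mm,
                 sine_periods = sine_periods,
                 lumen_radius_mm = lumen_radius_mm,
                 wall_thickness_mm = wall_thickness_mm,
                 aneurysm = aneurysm, root_features = root_features,
                 hu = hu_model, calc_fraction = calc_fraction,
                 calc_blob_radius_mm = calc_blob_radius_mm,
                 organs = organs, spacing_mm = spacing_mm,
                 margin_mm = margin_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# smoothly windowed sinusoidal lateral displacement on u in [0,1]:
# zero value and derivative at both ends
sine_window <- function(u, amplitude, periods) {
  amplitude * sin(pi * u)^2 * sin(2 * pi * periods * u)
}

#' Analytic phantom curve
#'
#' Builds the centerline of a phantom as an arc-length-parameterized C1
#' curve. The parameterization is established by dense numerical quadrature
#' (0.2 mm sampling), accurate to well below 0.1%.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_curve` with `pos(s)` and `tangent(s)`
#'   (vectorized over arc length `s` in mm, returning n x 3 matrices),
#'   `total_length_mm`, and the key constructed arc lengths in `$marks`.
#' @export
make_curve <- function(spec) {
  kind <- spec$curve_kind
  R <- spec$arch_radius_mm
  marks <- list()
  if (kind == "straight") {
    if (spec$length_mm <= 0) stop("degenerate curve: zero length")
    f <- function(q) cbind(0, 0, q)
    qmax <- spec$length_mm
  } else if (kind == "semicircle") {
    if (R <= 0) stop("degenerate curve: zero radius")
    f <- function(q) {
      th <- q / R * pi
      cbind(R * cos(th), 0, R * sin(th))
    }
    qmax <- R # q in [0, R] maps to theta in [0, pi]
  } else if (kind == "s_curve") {
    if (spec$length_mm <= 0) stop("degenerate curve: zero length")
    f <- function(q) {
      u <- q / spec$length_mm
      cbind(sine_window(u, spec$sine_amplitude_mm, spec$sine_periods), 0, q)
    }
    qmax <- spec$length_mm
  } else { # full_aorta
    H <- spec$abdominal_mm + spec$thoracic_mm
    A <- spec$ascending_mm
    if (H <= 0 || A <= 0 || R <= 0) stop("degenerate curve parameters")
    # lateral bow of the abdominal/descending run: two opposite-signed
    # sin^2 bumps (C1, zero value and slope at the window ends AND at the
    # diaphragm level, so landmark constructions stay unbiased); curvature
    # radius stays well above the lumen radius at the default amplitude
    z1 <- 0.2 * spec$abdominal_mm
    z2 <- 2 * spec$abdominal_mm - z1
    limb_x <- function(z) {
      x <- numeric(length(z))
      inw <- z > z1 & z < z2
      u <- (z[inw] - z1) / (z2 - z1)
      x[inw] <- spec$sine_amplitude_mm * sin(2 * pi * u)^2 * sign(0.5 - u)
      x
    }
    f <- function(q) {
      out <- matrix(0, length(q), 3)
      a <- q <= H
      out[a, ] <- cbind(limb_x(q[a]), 0, q[a])
      b <- q > H & q <= H + pi * R
      th <- (q[b] - H) / R
      out[b, ] <- cbind(0, R - R * cos(th), H + R * sin(th))
      cc <- q > H + pi * R
      out[cc, ] <- cbind(0, 2 * R, H - (q[cc] - H - pi * R))
      out
    }
    qmax <- H + pi * R + A
    marks$q_renal <- 0.4 * spec$abdominal_mm
    marks$q_diaphragm <- spec$abdominal_mm
    marks$q_arch <- function(theta) H + R * theta
  }
  qd <- seq(0, qmax, by = 0.2)
  if (length(qd) < 4) stop("degenerate curve: zero length")
  pd <- f(qd)
  seg <- sqrt(rowSums(diff(pd)^2))
  sd_ <- c(0, cumsum(seg))
  total <- sd_[length(sd_)]
  fx <- stats::splinefun(sd_, pd[, 1], method = "natural")
  fy <- stats::splinefun(sd_, pd[, 2], method = "natural")
  fz <- stats::splinefun(sd_, pd[, 3], method = "natural")
  pos <- function(s) {
    s <- pmin(pmax(s, 0), total)
    cbind(fx(s), fy(s), fz(s))
  }
  tangent <- function(s) {
    s <- pmin(pmax(s, 0), total)
    t <- cbind(fx(s, deriv = 1), fy(s, deriv = 1), fz(s, deriv = 1))
    t / sqrt(rowSums(t^2))
  }
  s_of_q <- stats::approxfun(qd, sd_)
  mk <- list()
  if (kind == "full_aorta") {
    mk$renal <- s_of_q(marks$q_renal)
    mk$diaphragm <- s_of_q(marks$q_diaphragm)
    mk$brachiocephalic <- s_of_q(marks$q_arch(0.75 * pi))
    mk$carotid <- s_of_q(marks$q_arch(0.5 * pi))
    mk$subclavian <- s_of_q(marks$q_arch(0.25 * pi))
    mk$ventricular_aortic <- total
    mk$bifurcation <- 0
    if (spec$root_features) {
      mk$sinus_valsalva <- total - 10
      mk$sinotubular_junction <- total - 24
      mk$annulus <- total
    }
  }
  structure(list(pos = pos, tangent = tangent, total_length_mm = total,
                 s_of_q = s_of_q, marks = mk, kind = kind),
            class = "phantom_curve")
}

# radius profile r(s) in mm for a spec/curve pair, vectorized
radius_profile <- function(spec, curve) {
  L <- curve$total_length_mm
  function(s) {
    r <- rep(spec$lumen_radius_mm, length(s))
    if (!is.null(spec$aneurysm)) {
      a <- spec$aneurysm
      r <- r + a$amplitude_mm * exp(-((s - a$center_mm) / a$width_mm)^2 / 2)
    }
    if (spec$root_features && spec$curve_kind == "full_aorta") {
      e <- L - s # distance from the valve end
      r <- r + 3.0 * exp(-((e - 10) / 3.5)^2 / 2) -
        1.5 * exp(-((e - 24) / 3.0)^2 / 2)
    }
    r
  }
}

# run code with a private, seeded RNG stream; restores the caller's state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# distance from grid points (3 coordinate arrays) to a segment A + t*u
segment_distance <- function(X, Y, Z, A, u, len) {
  dx <- X - A[1]; dy <- Y - A[2]; dz <- Z - A[3]
  t <- dx * u[1] + dy * u[2] + dz * u[3]
  t <- pmin(pmax(t, 0), len)
  sqrt((dx - t * u[1])^2 + (dy - t * u[2])^2 + (dz - t * u[3])^2)
}

ellipsoid_mask <- function(X, Y, Z, center, semi) {
  ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2 <= 1
}

#' Rasterize a phantom
#'
#' Produces the HU volume, the anatomical label map, and the analytic ground
#' truth for a phantom specification. Voxels are assigned by center-point
#' inclusion (no partial volume), so mask ground truth is exact.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `aorta_phantom` with elements `image`
#'   (an [image_volume()]), `labels` (an [label_volume()]) and `truth`
#'   (centerline samples, landmark arc lengths, tortuosity indices, radius
#'   profile, calcified fraction, true lumen mask).
#' @export
rasterize_phantom <- function(spec) {
  curve <- make_curve(spec)
  L <- curve$total_length_mm
  rfun <- radius_profile(spec, curve)
  sp <- spec$spacing_mm
  rmax <- max(rfun(seq(0, L, by = 0.5))) + spec$wall_thickness_mm

  # layout of auxiliary structures (world mm); full-aorta only
  organs <- list()
  if (spec$organs && spec$curve_kind == "full_aorta") {
    R <- spec$arch_radius_mm
    H <- spec$abdominal_mm + spec$thoracic_mm
    zd <- spec$abdominal_mm
    pe <- drop(curve$pos(L)); te <- drop(curve$tangent(L))
    arch_pt <- function(th) c(0, R - R * cos(th), H + R * sin(th))
    arch_rad <- function(th) c(0, -cos(th), sin(th))
    organs <- list(
      lv_blood = list(type = "ellipsoid", center = pe + 15 * te,
                      semi = c(20, 20, 18)),
      rv_blood = list(type = "ellipsoid", center = c(30, 30, zd + 25),
                      semi = c(16, 16, 16)),
      liver = list(type = "ellipsoid", center = c(30, 30, zd - 27),
                   semi = c(18, 18, 18)),
      kidney_left = list(type = "ellipsoid", center = c(-35, 5, 40),
                         semi = c(10, 8, 14)),
      kidney_right = list(type = "ellipsoid", center = c(35, 5, 40),
                          semi = c(10, 8, 14)),
      brachiocephalic_trunk = list(type = "tube", A = arch_pt(0.75 * pi),
                                   u = arch_rad(0.75 * pi), len = 20, rad = 4),
      left_common_carotid = list(type = "tube", A = arch_pt(0.5 * pi),
                                 u = arch_rad(0.5 * pi), len = 20, rad = 4),
      left_subclavian = list(type = "tube", A = arch_pt(0.25 * pi),
                             u = arch_rad(0.25 * pi), len = 20, rad = 4),
      iliac_left = list(type = "tube", A = c(-1.2, 0, -1.6),
                        u = c(-0.6, 0, -0.8), len = 40, rad = 6),
      iliac_right = list(type = "tube", A = c(1.2, 0, -1.6),
                         u = c(0.6, 0, -0.8), len = 40, rad = 6))
  }

  # grid bounds covering tube + organs + margin
  sdense <- seq(0, L, by = min(sp) * 0.4)
  pdense <- curve$pos(sdense)
  lo <- apply(pdense, 2, min) - rmax - spec$margin_mm
  hi <- apply(pdense, 2, max) + rmax + spec$margin_mm
  for (o in organs) {
    if (o$type == "ellipsoid") {
      lo <- pmin(lo, o$center - o$semi - spec$margin_mm)
      hi <- pmax(hi, o$center + o$semi + spec$margin_mm)
    } else {
      lo <- pmin(lo, pmin(o$A, o$A + o$len * o$u) - o$rad - spec$margin_mm)
      hi <- pmax(hi, pmax(o$A, o$A + o$len * o$u) + o$rad + spec$margin_mm)
    }
  }
  dims <- as.integer(ceiling((hi - lo) / sp)) + 1L
  origin <- lo

  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * sp[a])
  X <- array(rep(ax[[1]], times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ax[[2]], each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)

  # distance to the centerline + arc length of the nearest curve point,
  # via the feature transform of the rasterized dense curve samples
  geom <- list(spacing = sp, origin = origin, voxels = array(0L, dims))
  cidx <- world_to_voxel(geom, pdense)
  clin <- voxel_to_linear(dims, cidx)
  keep <- !duplicated(clin)
  clin <- clin[keep]
  cs <- sdense[keep]
  seed_mask <- array(FALSE, dims)
  seed_mask[clin] <- TRUE
  ft <- distance_transform(seed_mask, sp)
  s_near <- array(cs[match(ft$feature, clin)], dims)
  dist_c <- ft$dist
  # the feature transform measures distance to voxel-quantized curve points,
  # biasing the tube fat by ~a quarter voxel; refine shell voxels against the
  # analytic curve (0.1 mm samples in a local arc window)
  step_d <- 0.1
  sfine <- seq(0, L, by = step_d)
  pfine <- curve$pos(sfine)
  shell <- which(dist_c <= rmax + 2 * max(sp))
  offs <- -40:40 # +-4 mm arc window
  chunk_size <- 40000L
  for (lo_i in seq(1, length(shell), by = chunk_size)) {
    ch <- shell[lo_i:min(lo_i + chunk_size - 1L, length(shell))]
    i0 <- round(s_near[ch] / step_d) + 1L
    idx <- pmin(pmax(outer(i0, offs, "+"), 1L), length(sfine))
    d2 <- (matrix(pfine[idx, 1], length(ch)) - X[ch])^2 +
      (matrix(pfine[idx, 2], length(ch)) - Y[ch])^2 +
      (matrix(pfine[idx, 3], length(ch)) - Z[ch])^2
    jmin <- max.col(-d2, ties.method = "first")
    sel <- cbind(seq_along(ch), jmin)
    dist_c[ch] <- sqrt(d2[sel])
    s_near[ch] <- sfine[idx[sel]]
  }

  # flat end caps: cut the spherical caps the point-distance field produces
  p0 <- drop(curve$pos(0)); t0 <- drop(curve$tangent(0))
  p1 <- drop(curve$pos(L)); t1 <- drop(curve$tangent(L))
  cap <- rmax + 2 * max(sp)
  beyond <- (s_near < cap &
             (X - p0[1]) * t0[1] + (Y - p0[2]) * t0[2] + (Z - p0[3]) * t0[3] < 0) |
            (s_near > L - cap &
             (X - p1[1]) * t1[1] + (Y - p1[2]) * t1[2] + (Z - p1[3]) * t1[3] > 0)

  rr <- array(rfun(s_near), dims)
  lumen <- dist_c <= rr & !beyond
  wall <- dist_c <= rr + spec$wall_thickness_mm & !beyond & !lumen

  # calcification blobs at the lumen/wall interface, added until the target
  # fraction |calc| / (|lumen| + |calc|) is reached
  calc <- array(FALSE, dims)
  n_blobs <- 0L
  if (spec$calc_fraction > 0) {
    with_seed(spec$seed + 7L, {
      up <- c(0, 1, 0)
      for (i in 1:4000) {
        denom <- sum(lumen & !calc) + sum(calc)
        if (sum(calc) / denom >= spec$calc_fraction) break
        sc <- stats::runif(1, 0.08 * L, 0.92 * L)
        phi <- stats::runif(1, 0, 2 * pi)
        tg <- drop(curve$tangent(sc))
        nv <- up - sum(up * tg) * tg
        if (sqrt(sum(nv^2)) < 0.1) nv <- c(1, 0, 0) - tg[1] * tg
        nv <- nv / sqrt(sum(nv^2))
        bv <- c(tg[2] * nv[3] - tg[3] * nv[2],
                tg[3] * nv[1] - tg[1] * nv[3],
                tg[1] * nv[2] - tg[2] * nv[1])
        ctr <- drop(curve$pos(sc)) + rfun(sc) * (cos(phi) * nv + sin(phi) * bv)
        rb <- spec$calc_blob_radius_mm
        ii <- lapply(1:3, function(a) {
          rng <- floor((ctr[a] - rb - origin[a]) / sp[a]):
            ceiling((ctr[a] + rb - origin[a]) / sp[a]) + 1L
          rng[rng >= 1 & rng <= dims[a]]
        })
        if (any(lengths(ii) == 0)) next
        sub <- expand.grid(i = ii[[1]], j = ii[[2]], k = ii[[3]])
        w <- cbind(origin[1] + (sub$i - 1) * sp[1],
                   origin[2] + (sub$j - 1) * sp[2],
                   origin[3] + (sub$k - 1) * sp[3])
        inside <- rowSums(sweep(w, 2, ctr)^2) <= rb^2
        lin <- voxel_to_linear(dims, as.matrix(sub[inside, ]))
        lin <- lin[(lumen[lin] | wall[lin]) & !calc[lin]]
        if (!length(lin)) next
        calc[lin] <- TRUE
        n_blobs <- n_blobs + 1L
      }
    })
    lumen <- lumen & !calc
    wall <- wall & !calc
  }

  # organ masks (excluded from aorta voxels when assigning labels)
  organ_masks <- list()
  for (nm in names(organs)) {
    o <- organs[[nm]]
    organ_masks[[nm]] <- if (o$type == "ellipsoid")
      ellipsoid_mask(X, Y, Z, o$center, o$semi)
    else
      segment_distance(X, Y, Z, o$A, o$u, o$len) <= o$rad
  }

  # labels
  vocab <- default_vocabulary()
  lab <- array(0L, dims)
  aorta <- lumen | wall | calc
  for (nm in names(organ_masks))
    lab[organ_masks[[nm]] & !aorta] <- vocab[[nm]]
  lab[aorta] <- vocab[["aorta"]]

  # HU synthesis
  hu <- spec$hu
  n <- prod(dims)
  vox <- with_seed(spec$seed, {
    v <- stats::rnorm(n, hu$background_mean, hu$background_sd)
    for (nm in names(organ_masks)) {
      m <- organ_masks[[nm]] & !aorta
      v[m] <- stats::rnorm(sum(m), hu$organ_means[[nm]], hu$organ_sd)
    }
    v[wall] <- stats::rnorm(sum(wall), hu$wall_mean, hu$wall_sd)
    v[lumen] <- stats::rnorm(sum(lumen), hu$lumen_mean, hu$lumen_sd) +
      hu$lumen_gradient_hu_mm * dist_c[lumen]
    v[calc] <- stats::rnorm(sum(calc), hu$calc_mean, hu$calc_sd)
    if (hu$sp_fraction > 0) {
      in_a <- which(aorta & dist_c > 0.5 * rr)
      pick <- in_a[stats::runif(length(in_a)) < hu$sp_fraction]
      v[pick] <- v[pick] + sample(c(-1, 1), length(pick), replace = TRUE) *
        hu$sp_amplitude
    }
    array(v, dims)
  })

  # ground truth; for the bifurcation the constructed truth is the junction
  # rule applied to the exact masks (the most superior aorta point reached by
  # both dilated iliacs), projected onto the analytic curve
  if (!is.null(organ_masks$iliac_left) && !is.null(organ_masks$iliac_right)) {
    m <- (lumen | wall | calc) &
      dilate_mask(organ_masks$iliac_left, 5, sp) &
      dilate_mask(organ_masks$iliac_right, 5, sp)
    if (any(m)) {
      occ <- which(apply(m, 3, any))
      k <- max(occ)
      sl <- array(FALSE, dims); sl[, , k] <- m[, , k]
      com <- colMeans(linear_to_world(geom, which(sl)))
      sfine2 <- seq(0, L, by = 0.25)
      pf <- curve$pos(sfine2)
      curve$marks$bifurcation <-
        sfine2[which.min((pf[, 1] - com[1])^2 + (pf[, 2] - com[2])^2 +
                           (pf[, 3] - com[3])^2)]
    }
  }
  s_samp <- seq(0, L, by = 1)
  truth <- list(
    centerline = cbind(curve$pos(s_samp), arc_length_mm = s_samp),
    total_length_mm = L,
    landmarks_mm = unlist(curve$marks),
    radius_mm = cbind(s = s_samp, r = rfun(s_samp)),
    lumen_mask = lumen,
    calc_mask = calc,
    calc_fraction = if (sum(lumen) + sum(calc) > 0)
      sum(calc) / (sum(lumen) + sum(calc)) else 0,
    n_calc_blobs = n_blobs,
    tortuosity = phantom_truth_tortuosity(curve),
    curve = curve,
    spec = spec)

  structure(list(image = image_volume(vox, sp, origin),
                 labels = label_volume(lab, sp, origin, vocab),
                 truth = truth),
            class = "aorta_phantom")
}

# analytic tortuosity indices between constructed anchors (dense polyline)
phantom_truth_tortuosity <- function(curve) {
  ti <- function(s0, s1) {
    ss <- seq(s0, s1, length.out = max(64, ceiling(abs(s1 - s0))))
    p <- curve$pos(ss)
    arc <- sum(sqrt(rowSums(diff(p)^2)))
    chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    list(centerline_length_mm = arc, geometric_length_mm = chord,
         index = arc / chord)
  }
  out <- list(full_span = ti(0, curve$total_length_mm))
  mk <- curve$marks
  if (!is.null(mk$diaphragm)) {
    distal_arch <- mk$subclavian - 20
    out$descending <- ti(mk$diaphragm, distal_arch)
    out$full_aortic <- ti(mk$bifurcation, mk$ventricular_aortic)
  }
  out
}

#' Crop a phantom along the superior-inferior axis
#'
#' Emulates restricted fields of view: a cardiac crop removes the arch top
#' and everything below the heart, leaving the aorta as two disconnected
#' components; an abdominal crop removes everything above the upper abdomen.
#'
#' @param ph an `aorta_phantom`.
#' @param z_range_mm world z interval to keep, `c(lo, hi)`.
#' @return A cropped `aorta_phantom` (truth keeps the original landmark arc
#'   lengths plus the crop window under `$truth$crop_mm`).
#' @export
crop_phantom <- function(ph, z_range_mm) {
  sp <- ph$image$spacing
  org <- ph$image$origin
  d <- dim(ph$image$voxels)
  zw <- org[3] + (seq_len(d[3]) - 1) * sp[3]
  k <- which(zw >= z_range_mm[1] & zw <= z_range_mm[2])
  if (length(k) < 2) stop("crop window outside phantom")
  new_origin <- c(org[1], org[2], zw[k[1]])
  img <- image_volume(ph$image$voxels[, , k, drop = FALSE], sp, new_origin)
  lab <- label_volume(ph$labels$voxels[, , k, drop = FALSE], sp, new_origin,
                      ph$labels$vocabulary)
  truth <- ph$truth
  truth$lumen_mask <- truth$lumen_mask[, , k, drop = FALSE]
  truth$calc_mask <- truth$calc_mask[, , k, drop = FALSE]
  truth$crop_mm <- z_range_mm
  structure(list(image = img, labels = lab, truth = truth),
            class = "aorta_phantom")
}

#' Ready-made phantoms
#'
#' Convenience constructors for the standard test conditions: a full aorta
#' with organs; a cropped two-component cardiac field of view; a cropped
#' abdominal field of view; and a non-contrast scan (unenhanced blood HU
#' equal to the wall mean, with heavy peripheral partial-volume/streak
#' outliers, so HU thresholding yields a porous lumen surface).
#'
#' @param seed RNG seed.
#' @param ... overrides passed to [phantom_spec()].
#' @return An `aorta_phantom`.
#' @export
full_aorta_phantom <- function(seed = 1L, ...) {
  rasterize_phantom(phantom_spec(curve_kind = "full_aorta", seed = seed,
                                 sine_amplitude_mm = 10, ...))
}

#' @rdname full_aorta_phantom
#' @export
cardiac_phantom <- function(seed = 1L, ...) {
  ph <- full_aorta_phantom(seed = seed, ...)
  H <- ph$truth$spec$abdominal_mm + ph$truth$spec$thoracic_mm
  crop_phantom(ph, c(ph$truth$spec$abdominal_mm + 2, H - 15))
}

#' @rdname full_aorta_phantom
#' @export
abdominal_phantom <- function(seed = 1L, ...) {
  ph <- full_aorta_phantom(seed = seed, ...)
  crop_phantom(ph, c(min(ph$image$origin[3], -50),
                     ph$truth$spec$abdominal_mm + 20))
}

#' @rdname full_aorta_phantom
#' @export
noncontrast_phantom <- function(seed = 1L, ...) {
  rasterize_phantom(phantom_spec(curve_kind = "full_aorta", seed = seed,
                                 sine_amplitude_mm = 10,
                                 hu = list(lumen_mean = 50, lumen_sd = 15,
                                           wall_mean = 50,
                                           sp_fraction = 0.45,
                                           sp_amplitude = 600), ...))
}

#' Write a phantom to disk
#'
#' Writes `image.nii.gz`, `labels.nii.gz` and `truth.json` (numeric ground
#' truth only) into a directory.
#'
#' @param ph an `aorta_phantom`.
#' @param dir output directory (created if needed).
#' @param basename file name stem, default `"phantom"`.
#' @return The directory, invisibly.
#' @export
write_phantom <- function(ph, dir, basename = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(ph$image, file.path(dir, paste0(basename, "_image.nii.gz")))
  write_volume(ph$labels, file.path(dir, paste0(basename, "_labels.nii.gz")))
  tr <- ph$truth
  json <- list(total_length_mm = tr$total_length_mm,
               landmarks_mm = as.list(tr$landmarks_mm),
               calc_fraction = tr$calc_fraction,
               tortuosity = tr$tortuosity,
               centerline = unname(apply(tr$centerline, 1, as.list)))
  jsonlite::write_json(json, file.path(dir, paste0(basename, "_truth.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
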