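# Centerline extraction: scan-class-dependent endpoints, a medial path
# through the lumen (distance-transform-weighted shortest path, tracking the
# centers of maximally inscribed spheres), a smoothing-spline fit, and
# rotation-minimizing local frames with the consecutive-normal flip rule.

# centre of mass (world mm) of a mask
mask_com <- function(mask, vol) {
  idx <- which(mask)
  if (!length(idx)) stop("empty mask")
  colMeans(linear_to_world(vol, idx))
}

# COM of the voxels on the topmost (or bottommost) occupied z-slice of a mask
boundary_slice_com <- function(mask, vol, top = TRUE) {
  occ <- which(apply(mask, 3, any))
  k <- if (top) max(occ) else min(occ)
  sl <- array(FALSE, dim(mask))
  sl[, , k] <- mask[, , k]
  mask_com(sl, vol)
}

# ventricular-aortic junction point: COM of the overlap of the dilated LV
# blood pool and the dilated lumen (shared with the landmark module)
lv_junction_point <- function(lumen_mask, lv_mask, vol, dilation_mm) {
  ov <- dilate_mask(lv_mask, dilation_mm, vol$spacing) &
    dilate_mask(lumen_mask, dilation_mm, vol$spacing)
  if (!any(ov)) return(NULL)
  mask_com(ov, vol)
}

# move a point to the locally deepest voxel of a mask (largest distance to
# boundary within radius_mm), so paths start on the medial axis instead of
# the vessel surface
medial_snap <- function(point, mask, vol, radius_mm = 10) {
  dtb <- distance_to_boundary(mask, vol$spacing)
  idx <- which(mask)
  w <- linear_to_world(vol, idx)
  d2 <- (w[, 1] - point[1])^2 + (w[, 2] - point[2])^2 + (w[, 3] - point[3])^2
  near <- d2 <= radius_mm^2
  if (!any(near)) near <- d2 <= min(d2) + 1e-9
  best <- idx[near][which.max(dtb[idx[near]])]
  drop(linear_to_world(vol, best))
}

# iliac bifurcation: most superior point where the dilations of both iliac
# labels meet the aorta. The anatomical rule point is kept for the landmark;
# the path start is additionally recentred onto the medial axis so the
# first stretch of the centerline is not dragged along the vessel surface.
bifurcation_point <- function(aorta_mask, labels, vol, dilation_mm) {
  il <- structure_mask(labels, "iliac_left")
  ir <- structure_mask(labels, "iliac_right")
  if (!any(il) || !any(ir))
    stop("missing iliac labels: cannot locate the bifurcation")
  m <- aorta_mask &
    dilate_mask(il, dilation_mm, vol$spacing) &
    dilate_mask(ir, dilation_mm, vol$spacing)
  if (!any(m)) stop("iliac dilations do not reach the aorta")
  p <- boundary_slice_com(m, vol, top = TRUE)
  list(rule_point = p,
       start = medial_snap(p, aorta_mask, vol, radius_mm = 2 * dilation_mm))
}

#' Determine centerline endpoints per scan class
#'
#' Full aorta: from the iliac bifurcation to the left-ventricle junction.
#' Abdominal: from the bifurcation to where the lumen crosses the superior
#' scan boundary. Cardiac (two-part): the descending component uses its scan
#' entry and exit points; the ascending component starts where it leaves the
#' scan and ends at the LV junction.
#'
#' @param lumen_mask logical 3-D lumen array.
#' @param labels an [label_volume()].
#' @param scan_class `"full"`, `"abdominal"` or `"cardiac_two_part"`.
#' @param vol the [image_volume()] (geometry).
#' @param config an [pipeline_config()].
#' @return A list of endpoint pairs; each has `start`, `end` (world mm),
#'   `rule`, `name`, and for cardiac scans a `component` mask.
#' @export
determine_endpoints <- function(lumen_mask, labels, scan_class, vol,
                                config = pipeline_config()) {
  dil <- config$artery_dilation_mm
  if (scan_class == "full") {
    bif <- bifurcation_point(lumen_mask, labels, vol, dil)
    lv <- structure_mask(labels, "lv_blood")
    if (!any(lv)) stop("missing lv_blood label for a full-aorta scan")
    end <- lv_junction_point(lumen_mask, lv, vol, dil)
    if (is.null(end)) stop("LV does not meet the lumen")
    list(list(start = bif$start, bifurcation = bif$rule_point, end = end,
              rule = c("iliac bifurcation", "LV junction"), name = "aorta"))
  } else if (scan_class == "abdominal") {
    bif <- bifurcation_point(lumen_mask, labels, vol, dil)
    end <- boundary_slice_com(lumen_mask, vol, top = TRUE)
    list(list(start = bif$start, bifurcation = bif$rule_point, end = end,
              rule = c("iliac bifurcation", "scan boundary"), name = "aorta"))
  } else if (scan_class == "cardiac_two_part") {
    lab <- connected_components(lumen_mask)
    n <- attr(lab, "n_components")
    if (n < 2) stop("cardiac scan class but lumen has a single component")
    sizes <- tabulate(lab[lab > 0L], nbins = n)
    big <- order(sizes, decreasing = TRUE)[1:2]
    lv <- structure_mask(labels, "lv_blood")
    pairs <- list()
    for (ci in big) {
      comp <- array(lab == ci, dim(lumen_mask))
      j <- if (any(lv)) lv_junction_point(comp, lv, vol, dil) else NULL
      if (!is.null(j)) {
        start <- boundary_slice_com(comp, vol, top = TRUE)
        pairs[[length(pairs) + 1]] <-
          list(start = start, end = j,
               rule = c("scan boundary", "LV junction"),
               name = "ascending", component = comp)
      } else {
        pairs[[length(pairs) + 1]] <-
          list(start = boundary_slice_com(comp, vol, top = FALSE),
               end = boundary_slice_com(comp, vol, top = TRUE),
               rule = c("scan boundary", "scan boundary"),
               name = "descending", component = comp)
      }
    }
    pairs
  } else {
    stop("no endpoint rule for scan class: ", scan_class)
  }
}

# snap a world point to the nearest TRUE voxel of a mask (linear index)
snap_to_mask <- function(point, mask, vol) {
  idx <- which(mask)
  w <- linear_to_world(vol, idx)
  d2 <- (w[, 1] - point[1])^2 + (w[, 2] - point[2])^2 + (w[, 3] - point[3])^2
  idx[which.min(d2)]
}

#' Extract a raw medial centerline
#'
#' Minimal-cost route over the in-lumen voxel graph (26-connectivity) with
#' edge cost `step_length / (eps + distance_to_boundary)`, which penalizes
#' wall-hugging routes so the path follows the centers of maximally inscribed
#' spheres. Endpoints snap to the nearest in-lumen voxel.
#'
#' @param lumen_mask logical 3-D array.
#' @param endpoints one endpoint pair from [determine_endpoints()] (or any
#'   list with `start`/`end` world points).
#' @param vol the [image_volume()] (geometry).
#' @param config an [pipeline_config()].
#' @return Matrix of ordered path points (world mm), with the per-point
#'   distance-to-boundary as attribute `dtb`.
#' @export
extract_centerline <- function(lumen_mask, endpoints, vol,
                               config = pipeline_config()) {
  if (!any(lumen_mask)) stop("empty lumen mask")
  dtb <- distance_to_boundary(lumen_mask, vol$spacing)
  s_lin <- snap_to_mask(endpoints$start, lumen_mask, vol)
  e_lin <- snap_to_mask(endpoints$end, lumen_mask, vol)
  path <- cpp_medial_path(as.logical(lumen_mask), as.numeric(dtb),
                          as.integer(dim(lumen_mask)),
                          as.numeric(vol$spacing),
                          as.integer(s_lin), as.integer(e_lin),
                          config$medial_eps_mm)
  if (!length(path))
    stop("no route between endpoints: lumen disconnected")
  pts <- linear_to_world(vol, path)
  attr(pts, "dtb") <- dtb[path]
  pts
}

#' Fit a smoothing spline to a raw centerline path
#'
#' Each coordinate is fit as a cubic smoothing spline against cumulative
#' chord length. The spline's flexibility is set as a fixed density of
#' degrees of freedom per mm of vessel (default 0.3/mm, i.e. one effective
#' parameter per ~3 mm): anatomical curvature at wavelengths above roughly
#' 10 mm is preserved while the voxel-scale staircase of the discrete medial
#' path - which would otherwise inflate arc lengths and tortuosity - is
#' suppressed. The fit is resampled at a uniform arc-length step.
#'
#' @param raw_path matrix of ordered points (world mm).
#' @param step_mm arc-length sampling step (default 1 mm).
#' @param df_per_mm degrees of freedom per mm of path length; `NULL` selects
#'   the smoothness by generalized cross-validation (appropriate once the
#'   path noise is small and uncorrelated, e.g. after recentering).
#' @return A list of class `centerline`: `samples` (n x 3 mm), `arc_length`
#'   (mm, strictly increasing from 0), `total_length_mm`, `tangents`, and
#'   `frames = NULL` until [compute_frames()] is called.
#' @export
fit_smoothing_spline <- function(raw_path, step_mm = 1, df_per_mm = 0.3) {
  raw_path <- as.matrix(raw_path)
  keep <- c(TRUE, rowSums(abs(diff(raw_path))) > 1e-9)
  raw_path <- raw_path[keep, , drop = FALSE]
  n <- nrow(raw_path)
  if (n < 4) stop("too few path points for spline fitting")
  tch <- c(0, cumsum(sqrt(rowSums(diff(raw_path)^2))))
  if (tch[n] <= 0) stop("zero-length path")
  fit1 <- function(a, df) {
    if (is.null(df)) {
      # generalized cross-validation, with the flexibility capped so one
      # noisy realization cannot pull the fit into interpolating jitter
      cap <- min(max(4, tch[n] * 0.6), n - 1)
      f <- tryCatch(stats::smooth.spline(tch, raw_path[, a],
                                         keep.data = FALSE),
                    error = function(e) NULL)
      if (is.null(f) || f$df > cap)
        f <- stats::smooth.spline(tch, raw_path[, a], df = cap,
                                  keep.data = FALSE)
      f
    } else {
      stats::smooth.spline(tch, raw_path[, a],
                           df = min(max(4, tch[n] * df_per_mm), n - 1),
                           keep.data = FALSE)
    }
  }
  fits <- lapply(1:3, fit1, df = df_per_mm)

  # arc-length reparameterization on a dense evaluation of the fit
  td <- seq(0, tch[n], by = step_mm / 8)
  pd <- vapply(fits, function(f) stats::predict(f, td)$y, numeric(length(td)))
  sd_ <- c(0, cumsum(sqrt(rowSums(diff(pd)^2))))
  total <- sd_[length(sd_)]
  # samples sit on multiples of the step, except that the final sample is
  # placed at the true end so coverage is not truncated; the slice count
  # is exactly floor(length / step) + 1
  s_grid <- (0:floor(total / step_mm + 1e-9)) * step_mm
  s_grid[length(s_grid)] <- total
  t_of_s <- stats::approx(sd_, td, xout = s_grid, rule = 2)$y
  samples <- vapply(fits, function(f) stats::predict(f, t_of_s)$y,
                    numeric(length(s_grid)))
  tg <- vapply(fits, function(f) stats::predict(f, t_of_s, deriv = 1)$y,
               numeric(length(s_grid)))
  tg <- tg / sqrt(rowSums(tg^2))
  structure(list(samples = samples,
                 arc_length = s_grid,
                 total_length_mm = total,
                 tangents = tg,
                 frames = NULL,
                 step_mm = step_mm),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d samples, %.1f mm, step %.2g mm, frames %s\n",
              nrow(x$samples), x$total_length_mm, x$step_mm,
              if (is.null(x$frames)) "not set" else "set"))
  invisible(x)
}

# extend a resampled centerline along its end tangents to the lumen surface
# (the medial path ends at voxel centers, slightly inside the vessel)
extend_centerline <- function(cl, lumen_mask, vol, max_mm = 10) {
  num <- array(as.numeric(lumen_mask), dim(lumen_mask))
  step <- cl$step_mm / 4
  n <- nrow(cl$samples)
  # local curvature vector at an end (change of tangent per mm), capped so a
  # noisy estimate cannot swing the extension; lets the extension continue a
  # bend instead of leaving the curve tangentially
  end_curvature <- function(i1, i2) {
    k <- (cl$tangents[i2, ] - cl$tangents[i1, ]) /
      max(cl$arc_length[i2] - cl$arc_length[i1], 1e-6)
    nk <- sqrt(sum(k^2))
    if (nk < 0.01) return(c(0, 0, 0)) # below noise level: treat as straight
    if (nk > 0.05) k <- k * 0.05 / nk
    k
  }
  grow <- function(point, dir, curv) {
    out <- NULL
    hit_boundary <- FALSE
    p <- point
    for (k in seq_len(max(1, floor(max_mm / step)))) {
      p <- p + step * dir
      dir <- dir + step * curv
      dir <- dir / sqrt(sum(dir^2))
      v <- cpp_sample_volume(num, dim(lumen_mask), vol$spacing, vol$origin,
                             matrix(p, 1), 0, TRUE)
      if (v < 0.5) { hit_boundary <- TRUE; break }
      out <- rbind(out, unname(p))
    }
    # only extend when the lumen surface is reached within max_mm; otherwise
    # the end is not a truncated vessel end and extending would add a
    # spurious lead-in through the lumen interior
    if (hit_boundary) out else NULL
  }
  # extension direction: the averaged tangent of the outermost samples
  # (variance-reduced relative to the boundary tangent of the fit), rotated
  # forward by the local curvature to the end position
  iw <- min(11, n)
  end_dir <- function(idx, sign, curv) {
    d <- sign * colMeans(cl$tangents[idx, , drop = FALSE])
    mid <- mean(cl$arc_length[idx])
    endp <- if (sign > 0) cl$arc_length[n] else cl$arc_length[1]
    d <- d + abs(endp - mid) * curv
    d / sqrt(sum(d^2))
  }
  kh <- end_curvature(1, iw)
  kt <- end_curvature(max(1, n - 10), n)
  ih <- seq_len(min(5, n))
  it <- seq.int(max(1, n - 4), n)
  head_ext <- grow(cl$samples[1, ], end_dir(ih, -1, kh), kh)
  tail_ext <- grow(cl$samples[n, ], end_dir(it, +1, kt), kt)
  if (is.null(head_ext) && is.null(tail_ext)) return(cl)
  pts <- rbind(if (!is.null(head_ext)) head_ext[rev(seq_len(nrow(head_ext))), , drop = FALSE],
               cl$samples,
               tail_ext)
  resample_polyline(pts, cl$step_mm)
}

# uniform arc-length resampling of a polyline; tangents by central difference
resample_polyline <- function(pts, step_mm) {
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  dimnames(pts) <- NULL
  sd_ <- c(0, cumsum(unname(sqrt(rowSums(diff(pts)^2)))))
  total <- unname(sd_[length(sd_)])
  s_grid <- (0:floor(total / step_mm + 1e-9)) * step_mm
  s_grid[length(s_grid)] <- total
  samples <- vapply(1:3, function(a)
    stats::approx(sd_, pts[, a], xout = s_grid)$y, numeric(length(s_grid)))
  m <- nrow(samples)
  tg <- samples[pmin(1:m + 1, m), ] - samples[pmax(1:m - 1, 1), ]
  tg <- tg / sqrt(rowSums(tg^2))
  structure(list(samples = samples, arc_length = s_grid,
                 total_length_mm = total, tangents = tg, frames = NULL,
                 step_mm = step_mm),
            class = "centerline")
}

#' Compute regularized local frames along a centerline
#'
#' Propagates an initial normal (the up-vector orthogonalized against the
#' first tangent) along the curve with the rotation-minimizing
#' double-reflection scheme, which avoids the sharp frame changes of the
#' naive Frenet construction at inflections. After propagation the flip rule
#' is enforced: if the dot product between consecutive normals is negative,
#' the current normal (and binormal) is flipped.
#'
#' @param centerline a [fit_smoothing_spline()] result.
#' @param up_vector initial normal direction; default anterior `(0, 1, 0)`,
#'   with a lateral fallback when near-parallel to the first tangent.
#' @return The centerline with `frames = list(normal, binormal)` (each
#'   n x 3, orthonormal with the tangents).
#' @export
compute_frames <- function(centerline, up_vector = c(0, 1, 0)) {
  tg <- centerline$tangents
  x <- centerline$samples
  n <- nrow(x)
  if (any(!is.finite(tg))) stop("degenerate tangent")
  r <- up_vector - sum(up_vector * tg[1, ]) * tg[1, ]
  if (sqrt(sum(r^2)) < 1e-6) {
    up_vector <- c(1, 0, 0)
    r <- up_vector - sum(up_vector * tg[1, ]) * tg[1, ]
    if (sqrt(sum(r^2)) < 1e-6) stop("up_vector parallel to the first tangent")
  }
  r <- r / sqrt(sum(r^2))
  normal <- matrix(0, n, 3)
  normal[1, ] <- r
  for (i in seq_len(n - 1)) {
    v1 <- x[i + 1, ] - x[i, ]
    c1 <- sum(v1^2)
    if (c1 < 1e-12) { normal[i + 1, ] <- normal[i, ]; next }
    rL <- normal[i, ] - (2 / c1) * sum(v1 * normal[i, ]) * v1
    tL <- tg[i, ] - (2 / c1) * sum(v1 * tg[i, ]) * v1
    v2 <- tg[i + 1, ] - tL
    c2 <- sum(v2^2)
    rn <- if (c2 < 1e-12) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    rn <- rn - sum(rn * tg[i + 1, ]) * tg[i + 1, ]
    rn <- rn / sqrt(sum(rn^2))
    # flip rule: never let consecutive normals reverse
    if (sum(rn * normal[i, ]) < 0) rn <- -rn
    normal[i + 1, ] <- rn
  }
  binormal <- cbind(tg[, 2] * normal[, 3] - tg[, 3] * normal[, 2],
                    tg[, 3] * normal[, 1] - tg[, 1] * normal[, 3],
                    tg[, 1] * normal[, 2] - tg[, 2] * normal[, 1])
  centerline$frames <- list(normal = normal, binormal = binormal)
  centerline
}

# recentre each sample onto the center of mass of its orthogonal lumen
# cross-section (the discrete medial path can sit up to a voxel off-axis at
# bends, where the distance-to-boundary plateau is quantization-flat);
# slices with degenerate area (end caps) keep their position
recenter_centerline <- function(cl, lumen_mask, vol, config) {
  cl <- compute_frames(cl)
  cfg <- config
  cfg$cpr_inplane_res_mm <- max(0.5, config$cpr_inplane_res_mm)
  cfg$cpr_halfwidth_mm <- min(config$cpr_halfwidth_mm, 25)
  st <- straighten(image_volume(array(0, dim(lumen_mask)), vol$spacing,
                                vol$origin),
                   lumen_mask, cl, cfg)
  m <- dim(st$lumen_slices)[1]
  c0 <- (m + 1) / 2
  counts <- apply(st$lumen_slices, 3, sum)
  med <- stats::median(counts[counts > 0])
  # only trust slices that look like clean cross-sections: strongly tilted
  # planes (elongated sections) and partial end-cap cuts are left alone, and
  # a displacement cap guards against residual outliers
  ok <- counts >= 0.6 * med & counts <= 1.4 * med
  out <- cl$samples
  for (i in which(ok)) {
    px <- which(st$lumen_slices[, , i], arr.ind = TRUE)
    du <- (mean(px[, 1]) - c0) * cfg$cpr_inplane_res_mm
    dv <- (mean(px[, 2]) - c0) * cfg$cpr_inplane_res_mm
    shift <- sqrt(du^2 + dv^2)
    if (shift > 3) { du <- du * 3 / shift; dv <- dv * 3 / shift }
    out[i, ] <- cl$samples[i, ] + du * cl$frames$normal[i, ] +
      dv * cl$frames$binormal[i, ]
  }
  out
}

#' Full centerline pipeline for one lumen component
#'
#' Chains [extract_centerline()], [fit_smoothing_spline()], one pass of
#' cross-sectional recentering (each sample moved to the center of mass of
#' its orthogonal lumen section, then refit), extension of the fitted curve
#' to the lumen surface along the end tangents, and [compute_frames()].
#'
#' @inheritParams extract_centerline
#' @return A `centerline` with frames set.
#' @export
centerline_pipeline <- function(lumen_mask, endpoints, vol,
                                config = pipeline_config()) {
  raw <- extract_centerline(lumen_mask, endpoints, vol, config)
  # the first/last couple of voxels are endpoint-snap artifacts (diagonal
  # first steps that corrupt the spline's boundary tangents); trim them and
  # let the boundary extension restore true vessel-end coverage
  if (nrow(raw) > 12) raw <- raw[3:(nrow(raw) - 2), , drop = FALSE]
  cl <- fit_smoothing_spline(raw, step_mm = config$cpr_slice_step_mm,
                             df_per_mm = config$spline_df_per_mm)
  # two recentering passes: the second corrects the residual off-axis bias
  # at bends, where the first pass measured the offsets in slightly tilted
  # planes. The recentred points carry only small, uncorrelated noise, so
  # the refits choose their smoothness by generalized cross-validation.
  for (it in 1:2) {
    ctr <- recenter_centerline(cl, lumen_mask, vol, config)
    cl <- fit_smoothing_spline(ctr, step_mm = config$cpr_slice_step_mm,
                               df_per_mm = NULL)
  }
  # the boundary samples of a smoothing spline carry the largest variance;
  # drop them and let the extension regrow the ends from interior-quality
  # positions and directions
  n <- nrow(cl$samples)
  if (n > 8)
    cl <- resample_polyline(cl$samples[3:(n - 2), , drop = FALSE],
                            config$cpr_slice_step_mm)
  cl <- extend_centerline(cl, lumen_mask, vol,
                          max_mm = config$centerline_extend_mm)
  compute_frames(cl)
}

# index of the centerline sample nearest to a world point
nearest_sample <- function(centerline, point) {
  d2 <- (centerline$samples[, 1] - point[1])^2 +
    (centerline$samples[, 2] - point[2])^2 +
    (centerline$samples[, 3] - point[3])^2
  which.min(d2)
}
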