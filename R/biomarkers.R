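# Quantitative biomarkers: maximal diameters per anatomical segment,
# tortuosity indices, and agreement statistics against manual readings.

# bilinear interpolation of a matrix at fractional pixel coordinates
# (1-based); outside values are 0
bilinear <- function(M, x, y) {
  nx <- nrow(M); ny <- ncol(M)
  x0 <- floor(x); y0 <- floor(y)
  tx <- x - x0; ty <- y - y0
  ok <- x0 >= 1 & x0 + 1 <= nx & y0 >= 1 & y0 + 1 <= ny
  v <- numeric(length(x))
  if (any(ok)) {
    i <- x0[ok]; j <- y0[ok]
    v00 <- M[cbind(i, j)];     v10 <- M[cbind(i + 1, j)]
    v01 <- M[cbind(i, j + 1)]; v11 <- M[cbind(i + 1, j + 1)]
    v[ok] <- v00 * (1 - tx[ok]) * (1 - ty[ok]) + v10 * tx[ok] * (1 - ty[ok]) +
      v01 * (1 - tx[ok]) * ty[ok] + v11 * tx[ok] * ty[ok]
  }
  v
}

#' Maximal diameter of a cross-sectional mask
#'
#' The maximally long line through the center of mass of the cross section
#' that hits its boundaries: for every angle in 1-degree steps, the chord is
#' the distance between the two boundary crossings of the ray through the
#' COM, with sub-pixel crossings by linear interpolation along the ray.
#'
#' @param slice_mask logical matrix (one straightened slice).
#' @param inplane_res_mm pixel size in mm.
#' @param angle_step_deg angular resolution of the search (default 1).
#' @return list with `max_diameter_mm`, `com` (pixel coords), `angle_deg`,
#'   and `degenerate` (TRUE when the COM falls outside the mask, e.g. a
#'   crescent-shaped section, or the mask is a single pixel).
#' @export
max_diameter <- function(slice_mask, inplane_res_mm, angle_step_deg = 1) {
  px <- which(slice_mask, arr.ind = TRUE)
  if (nrow(px) == 0) stop("empty slice mask")
  com <- colMeans(px)
  M <- matrix(as.numeric(slice_mask), nrow(slice_mask))
  if (nrow(px) == 1) {
    return(list(max_diameter_mm = inplane_res_mm, com = com, angle_deg = 0,
                degenerate = TRUE))
  }
  if (bilinear(M, com[1], com[2]) < 0.5) {
    warning("cross-section COM outside the mask (crescent-shaped section)")
    return(list(max_diameter_mm = 0, com = com, angle_deg = NA,
                degenerate = TRUE))
  }
  angles <- seq(0, 180 - angle_step_deg, by = angle_step_deg) * pi / 180
  # radial samples in pixel units, half-pixel steps out to the grid corner
  rmax <- sqrt(nrow(M)^2 + ncol(M)^2)
  tt <- seq(0, rmax, by = 0.5)
  half_chord <- function(dx, dy) {
    # first 0.5-crossing outward from the COM, per angle (vectorized)
    xs <- outer(dx, tt) + com[1]
    ys <- outer(dy, tt) + com[2]
    v <- matrix(bilinear(M, as.vector(xs), as.vector(ys)), nrow = length(dx))
    inside <- v >= 0.5
    # index of last step before the first outside sample
    first_out <- apply(inside, 1, function(r) {
      k <- which(!r)
      if (length(k)) k[1] else length(r)
    })
    k0 <- pmax(first_out - 1, 1)
    v0 <- v[cbind(seq_along(dx), k0)]
    v1 <- v[cbind(seq_along(dx), pmin(first_out, length(tt)))]
    frac <- ifelse(v0 > v1, (v0 - 0.5) / (v0 - v1), 0)
    tt[k0] + frac * 0.5
  }
  hp <- half_chord(cos(angles), sin(angles))
  hm <- half_chord(-cos(angles), -sin(angles))
  chords <- (hp + hm) * inplane_res_mm
  # a short circular running median over angles (+-4 degrees) suppresses
  # single-angle spikes from resampled-boundary jag; for smooth sections the
  # chord varies quadratically near its maximum, so the effect there is
  # negligible (< 0.01 mm on an ellipse with 15/10 mm semi-axes)
  k <- length(chords)
  if (k >= 9) {
    idx <- outer(seq_len(k), -4:4, "+")
    idx <- ((idx - 1) %% k) + 1
    chords <- apply(matrix(chords[idx], k), 1, stats::median)
  }
  best <- which.max(chords)
  list(max_diameter_mm = chords[best], com = com,
       angle_deg = (best - 1) * angle_step_deg, degenerate = FALSE)
}

#' Best-fit-ellipse aspect ratio of a cross-sectional mask
#'
#' The square root of the ratio of the two in-plane second-moment
#' eigenvalues; slices whose ratio exceeds the threshold fail (ratio equal to
#' the threshold passes).
#'
#' @param slice_mask logical matrix.
#' @param threshold maximum acceptable ratio.
#' @return list with `aspect_ratio` and `pass`.
#' @export
ellipse_aspect_check <- function(slice_mask, threshold = 2.5) {
  px <- which(slice_mask, arr.ind = TRUE)
  if (nrow(px) == 0) stop("empty slice mask")
  if (nrow(px) == 1) return(list(aspect_ratio = 1, pass = TRUE))
  cc <- stats::cov(px)
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  ratio <- sqrt(max(ev) / max(min(ev), 1e-12))
  list(aspect_ratio = ratio, pass = ratio <= threshold)
}

#' Per-segment diameter measurements
#'
#' For each available anatomical segment the measurement slice is the one
#' with the largest cross-sectional area inside the segment (ties break to
#' the lower arc length); the sinus of Valsalva, sinotubular junction and
#' annulus are measured at their landmark slices (area minima for the
#' latter two). The maximal diameter is computed on each selected slice; the
#' best-fit-ellipse aspect check flags unreliable slices.
#'
#' @param profile a [csa_profile()].
#' @param straightened the matching [straighten()] result.
#' @param segment_table a [partition_segments()] result.
#' @param root list of root landmarks from [root_landmarks()] (optional).
#' @param annulus_straightened optional straightened combined LV-aorta volume
#'   for the annulus measurement.
#' @param config an [pipeline_config()].
#' @return A data.frame of measurements: `name`, `segment`, `arc_length_mm`,
#'   `csa_mm2`, `max_diameter_mm`, `aspect_ratio`, `qc_pass`.
#' @export
measure_segments <- function(profile, straightened, segment_table,
                             root = NULL, annulus_straightened = NULL,
                             config = pipeline_config()) {
  res <- straightened$inplane_res_mm
  measure_slice <- function(str, i, name, segment) {
    sl <- str$lumen_slices[, , i]
    if (!any(sl))
      return(data.frame(name = name, segment = segment,
                        arc_length_mm = str$slice_arc_lengths[i],
                        csa_mm2 = 0, max_diameter_mm = NA_real_,
                        aspect_ratio = NA_real_, qc_pass = FALSE))
    md <- suppressWarnings(max_diameter(sl, str$inplane_res_mm))
    ec <- ellipse_aspect_check(sl, config$aspect_ratio_threshold)
    data.frame(name = name, segment = segment,
               arc_length_mm = str$slice_arc_lengths[i],
               csa_mm2 = sum(sl) * str$inplane_res_mm^2,
               max_diameter_mm = md$max_diameter_mm,
               aspect_ratio = ec$aspect_ratio,
               qc_pass = ec$pass && !md$degenerate)
  }
  out <- list()
  for (r in seq_len(nrow(segment_table))) {
    if (!segment_table$available[r]) next
    seg <- segment_table$segment[r]
    sel <- profile$arc_length_mm >= segment_table$start_mm[r] &
      profile$arc_length_mm <= segment_table$end_mm[r] & profile$valid
    if (!any(sel)) {
      warning("segment without valid slices: ", seg)
      next
    }
    i <- which(sel)[which.max(profile$area_mm2[sel])]
    out[[length(out) + 1]] <- measure_slice(straightened, i, seg, seg)
  }
  if (!is.null(root)) {
    for (nm in c("sinus_valsalva", "sinotubular_junction")) {
      lm <- root[[nm]]
      if (is.null(lm) || lm$missing) next
      i <- which.min(abs(straightened$slice_arc_lengths - lm$arc_length_mm))
      out[[length(out) + 1]] <- measure_slice(straightened, i, nm, "root")
    }
    lm <- root$annulus
    if (!is.null(lm) && !lm$missing && !is.null(annulus_straightened)) {
      i <- which.min(abs(annulus_straightened$slice_arc_lengths -
                           lm$arc_length_combined_mm))
      row <- measure_slice(annulus_straightened, i, "annulus", "root")
      row$arc_length_mm <- lm$arc_length_mm
      out[[length(out) + 1]] <- row
    }
  }
  if (!length(out))
    return(data.frame(name = character(), segment = character(),
                      arc_length_mm = numeric(), csa_mm2 = numeric(),
                      max_diameter_mm = numeric(), aspect_ratio = numeric(),
                      qc_pass = logical()))
  do.call(rbind, out)
}

#' Tortuosity index between two centerline positions
#'
#' The centerline length between the anchors divided by the Euclidean
#' distance between their world points; always at least 1. The descending
#' index uses the distal arch and diaphragm landmarks; the full aortic index
#' the bifurcation (centerline start) and the ventricular-aortic landmark.
#'
#' @param centerline a `centerline`.
#' @param landmark_a,landmark_b `aorta_landmark`s or arc lengths in mm.
#' @param name label for the result.
#' @return list of class `tortuosity_result`: `name`, `centerline_length_mm`,
#'   `geometric_length_mm`, `index`.
#' @export
tortuosity <- function(centerline, landmark_a, landmark_b, name = "tortuosity") {
  arc_of <- function(lm) {
    if (inherits(lm, "aorta_landmark")) {
      if (lm$missing) stop("missing landmark for tortuosity: ", lm$name)
      lm$arc_length_mm
    } else as.numeric(lm)
  }
  s1 <- arc_of(landmark_a); s2 <- arc_of(landmark_b)
  if (abs(s2 - s1) < 1e-9) stop("coincident landmarks")
  i1 <- which.min(abs(centerline$arc_length - s1))
  i2 <- which.min(abs(centerline$arc_length - s2))
  clen <- abs(centerline$arc_length[i2] - centerline$arc_length[i1])
  glen <- sqrt(sum((centerline$samples[i2, ] - centerline$samples[i1, ])^2))
  structure(list(name = name, centerline_length_mm = clen,
                 geometric_length_mm = glen, index = clen / glen),
            class = "tortuosity_result")
}

#' @export
print.tortuosity_result <- function(x, ...) {
  cat(sprintf("<tortuosity> %s: %.1f mm / %.1f mm = %.3f\n", x$name,
              x$centerline_length_mm, x$geometric_length_mm, x$index))
  invisible(x)
}

#' Agreement statistics between automatic and manual measurements
#'
#' Mean absolute error, mean absolute percentage error, bias (mean error),
#' Pearson correlation, coefficient of variation (the mean of the signed
#' per-pair difference over the per-pair average, as a percentage; an
#' absolute-value variant is available), and Bland-Altman limits of
#' agreement (bias +/- 1.96 sd of the differences).
#'
#' @param automatic,manual numeric vectors of paired measurements (n >= 2;
#'   manual values must be positive for the ratio metrics).
#' @param cv_absolute use `|a - m|` in the coefficient of variation.
#' @return list of class `agreement_stats`: `n`, `mae`, `mape_percent`,
#'   `bias`, `pearson_r`, `cv_percent`, `loa_low`, `loa_high`,
#'   `out_of_loa_fraction`.
#' @export
agreement_metrics <- function(automatic, manual, cv_absolute = FALSE) {
  a <- as.numeric(automatic); m <- as.numeric(manual)
  if (length(a) != length(m)) stop("paired vectors of equal length required")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  if (any(m <= 0)) stop("manual values must be positive for ratio metrics")
  d <- a - m
  cvterm <- d / ((a + m) / 2)
  if (cv_absolute) cvterm <- abs(cvterm)
  sd_d <- stats::sd(d)
  loa_low <- mean(d) - 1.96 * sd_d
  loa_high <- mean(d) + 1.96 * sd_d
  structure(list(n = n,
                 mae = mean(abs(d)),
                 mape_percent = 100 * mean(abs(d) / m),
                 bias = mean(d),
                 pearson_r = stats::cor(a, m),
                 cv_percent = 100 * mean(cvterm),
                 loa_low = loa_low, loa_high = loa_high,
                 out_of_loa_fraction = mean(d < loa_low | d > loa_high)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement> n=%d MAE=%.3g MAPE=%.3g%% bias=%.3g r=%.3f CV=%.3g%% LoA [%.3g, %.3g]\n",
              x$n, x$mae, x$mape_percent, x$bias, x$pearson_r, x$cv_percent,
              x$loa_low, x$loa_high))
  invisible(x)
}
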