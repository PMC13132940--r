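# Anatomical landmark detection. Landmarks are located from the organ label
# maps and projected onto the centerline; they partition the aorta into the
# standard anatomical segments (ascending, arch, descending, suprarenal,
# infrarenal). Arc-length convention: 0 at the iliac bifurcation, increasing
# toward the aortic valve, so "distal" (away from the heart) means
# decreasing arc length.

new_landmark <- function(name, arc_length_mm = NA_real_, point = NULL,
                         provenance = "", missing = FALSE, warning = NULL) {
  structure(list(name = name, arc_length_mm = arc_length_mm, point = point,
                 provenance = provenance, missing = missing,
                 warning = warning),
            class = "aorta_landmark")
}

#' @export
print.aorta_landmark <- function(x, ...) {
  if (x$missing)
    cat(sprintf("<landmark> %s: missing (%s)\n", x$name, x$warning))
  else
    cat(sprintf("<landmark> %s at %.1f mm [%s]\n", x$name, x$arc_length_mm,
                x$provenance))
  invisible(x)
}

landmark_at_sample <- function(centerline, i, name, provenance) {
  new_landmark(name, arc_length_mm = centerline$arc_length[i],
               point = centerline$samples[i, ], provenance = provenance)
}

#' Organ-overlap landmark
#'
#' Dilates both masks by a metric ball, computes the center of mass of their
#' overlap, and assigns the nearest centerline sample.
#'
#' @param lumen_mask,organ_mask logical 3-D arrays.
#' @param centerline a `centerline`.
#' @param vol the [image_volume()] (geometry).
#' @param dilation_mm ball radius (default 5 mm).
#' @param name landmark name.
#' @return An `aorta_landmark`; when the dilated masks do not meet, the
#'   landmark is returned with `missing = TRUE` and a warning message.
#' @export
overlap_landmark <- function(lumen_mask, organ_mask, centerline, vol,
                             dilation_mm = 5, name = "overlap") {
  if (!any(organ_mask))
    return(new_landmark(name, missing = TRUE, warning = "organ label empty"))
  if (!any(lumen_mask)) stop("empty lumen mask")
  ov <- dilate_mask(organ_mask, dilation_mm, vol$spacing) &
    dilate_mask(lumen_mask, dilation_mm, vol$spacing)
  if (!any(ov))
    return(new_landmark(name, missing = TRUE,
                        warning = "no overlap after dilation: structure too far from the lumen"))
  com <- mask_com(ov, vol)
  i <- nearest_sample(centerline, com)
  landmark_at_sample(centerline, i, name,
                     sprintf("overlap COM (%.0f, %.0f, %.0f) mm", com[1],
                             com[2], com[3]))
}

#' Aortic arch landmarks
#'
#' The proximal arch landmark sits at the origin of the brachiocephalic
#' trunk; the distal arch landmark is the left-subclavian projection shifted
#' `distal_arch_offset_mm` (2 cm) along arc length toward the descending
#' aorta, clamped to the centerline span with a warning if clamping occurs.
#'
#' @param lumen_mask logical lumen array.
#' @param labels an [label_volume()] with the arch branch structures.
#' @param centerline a `centerline`.
#' @param vol geometry.
#' @param config an [pipeline_config()].
#' @return list with elements `proximal_arch`, `distal_arch` and
#'   `left_subclavian`, `left_common_carotid` (reported, not used downstream).
#' @export
arch_landmarks <- function(lumen_mask, labels, centerline, vol,
                           config = pipeline_config()) {
  dil <- config$artery_dilation_mm
  prox <- overlap_landmark(lumen_mask, structure_mask(labels, "brachiocephalic_trunk"),
                           centerline, vol, dil, "proximal_arch")
  car <- overlap_landmark(lumen_mask, structure_mask(labels, "left_common_carotid"),
                          centerline, vol, dil, "left_common_carotid")
  sub <- overlap_landmark(lumen_mask, structure_mask(labels, "left_subclavian"),
                          centerline, vol, dil, "left_subclavian")
  if (sub$missing) {
    dist <- new_landmark("distal_arch", missing = TRUE,
                         warning = "left subclavian landmark missing")
  } else {
    s <- sub$arc_length_mm - config$distal_arch_offset_mm # distal = toward 0
    warn <- NULL
    if (s < 0) { s <- 0; warn <- "distal arch offset clamped to centerline start" }
    i <- which.min(abs(centerline$arc_length - s))
    dist <- landmark_at_sample(centerline, i, "distal_arch",
                               sprintf("left subclavian %+.0f mm distal",
                                       -config$distal_arch_offset_mm))
    dist$warning <- warn
  }
  list(proximal_arch = prox, distal_arch = dist,
       left_subclavian = sub, left_common_carotid = car)
}

# surface voxels of a mask (boundary shell one voxel thick), as world points
surface_points <- function(mask, vol) {
  er <- erode_mask(mask, min(vol$spacing), vol$spacing)
  linear_to_world(vol, which(mask & !er))
}

#' Diaphragm landmark
#'
#' Starting from the lowest (most inferior) right-ventricle surface point,
#' the shortest RV-liver surface distance is iteratively refined (closest
#' point on the liver, then closest point on the RV, and so on). The
#' midpoint of the converged pair estimates the diaphragm; the nearest
#' centerline sample becomes the landmark.
#'
#' @param rv_mask,liver_mask logical 3-D arrays.
#' @param centerline a `centerline`.
#' @param vol geometry.
#' @param tol_mm convergence tolerance on the pair distance (default 0.5).
#' @param max_iter iteration cap (default 50).
#' @return An `aorta_landmark` (missing with a warning when either organ is
#'   absent).
#' @export
diaphragm_landmark <- function(rv_mask, liver_mask, centerline, vol,
                               tol_mm = 0.5, max_iter = 50) {
  if (!any(rv_mask) || !any(liver_mask))
    return(new_landmark("diaphragm", missing = TRUE,
                        warning = "RV or liver label missing"))
  rvs <- surface_points(rv_mask, vol)
  lvs <- surface_points(liver_mask, vol)
  p <- rvs[which.min(rvs[, 3]), ]
  d_prev <- Inf
  q <- NULL
  for (k in seq_len(max_iter)) {
    d2l <- (lvs[, 1] - p[1])^2 + (lvs[, 2] - p[2])^2 + (lvs[, 3] - p[3])^2
    q <- lvs[which.min(d2l), ]
    d2r <- (rvs[, 1] - q[1])^2 + (rvs[, 2] - q[2])^2 + (rvs[, 3] - q[3])^2
    p_new <- rvs[which.min(d2r), ]
    d <- sqrt(min(d2r))
    if (d_prev - d < tol_mm) { p <- p_new; break }
    d_prev <- d
    p <- p_new
  }
  mid <- (p + q) / 2
  i <- nearest_sample(centerline, mid)
  lm <- landmark_at_sample(centerline, i, "diaphragm",
                           sprintf("RV-liver midpoint (%.0f, %.0f, %.0f) mm",
                                   mid[1], mid[2], mid[3]))
  lm$pair <- list(rv = p, liver = q, midpoint = mid)
  lm
}

#' Renal landmark
#'
#' The line through the two kidney centers of mass; the centerline sample
#' closest to that line becomes the landmark.
#'
#' @param kidney_left,kidney_right logical 3-D arrays.
#' @param centerline a `centerline`.
#' @param vol geometry.
#' @return An `aorta_landmark` (missing when a kidney label is absent).
#' @export
renal_landmark <- function(kidney_left, kidney_right, centerline, vol) {
  if (!any(kidney_left) || !any(kidney_right))
    return(new_landmark("renal", missing = TRUE,
                        warning = "kidney label missing"))
  c1 <- mask_com(kidney_left, vol)
  c2 <- mask_com(kidney_right, vol)
  u <- c2 - c1
  nu <- sqrt(sum(u^2))
  if (nu < 1e-6) stop("degenerate kidney line")
  u <- u / nu
  rel <- sweep(centerline$samples, 2, c1)
  t <- rel %*% u
  d2 <- rowSums((rel - t %*% t(u))^2)
  i <- which.min(d2)
  landmark_at_sample(centerline, i, "renal", "kidney COM line projection")
}

#' Aortic-root landmarks from the cross-sectional area profile
#'
#' The sinus of Valsalva is the largest cross-sectional area within 20 mm
#' distal to the ventricular-aortic landmark; the sinotubular junction the
#' smallest area between 5 and 25 mm beyond the sinus; the annulus the
#' smallest area within 10 mm proximal to the ventricular-aortic landmark
#' along the combined LV-aorta centerline. Windows beyond the available
#' profile leave the affected landmark missing with a warning; ties break
#' toward the window start.
#'
#' @param profile a [csa_profile()] of the aortic centerline.
#' @param ventricular_aortic the ventricular-aortic `aorta_landmark`.
#' @param centerline the aortic `centerline`.
#' @param annulus_profile optional [csa_profile()] of the combined LV-aorta
#'   centerline (see [lv_extension()]); with `annulus_centerline` and
#'   `annulus_va_mm`, the ventricular-aortic arc length on that line.
#' @param annulus_centerline,annulus_va_mm companion pieces for the annulus
#'   search.
#' @param config an [pipeline_config()] (root windows).
#' @return list with `sinus_valsalva`, `sinotubular_junction`, `annulus`
#'   landmarks.
#' @export
root_landmarks <- function(profile, ventricular_aortic, centerline,
                           annulus_profile = NULL,
                           annulus_centerline = NULL,
                           annulus_va_mm = NULL,
                           config = pipeline_config()) {
  rw <- config$root_windows_mm
  out <- list(
    sinus_valsalva = new_landmark("sinus_valsalva", missing = TRUE,
                                  warning = "window unavailable"),
    sinotubular_junction = new_landmark("sinotubular_junction", missing = TRUE,
                                        warning = "window unavailable"),
    annulus = new_landmark("annulus", missing = TRUE,
                           warning = "combined LV-aorta centerline unavailable"))
  if (ventricular_aortic$missing) {
    out$sinus_valsalva$warning <- "ventricular-aortic landmark missing"
    out$sinotubular_junction$warning <- "ventricular-aortic landmark missing"
    out$annulus$warning <- "ventricular-aortic landmark missing"
    return(out)
  }
  va <- ventricular_aortic$arc_length_mm
  # distal = decreasing arc length; window start = the end nearest va.
  # half-open (va excluded): the junction sample itself is not a sinus
  # candidate.
  sel_s <- profile$arc_length_mm < va &
    profile$arc_length_mm >= va - rw$sinus & profile$valid
  if (any(sel_s)) {
    cand <- which(sel_s)
    cand <- cand[order(-profile$arc_length_mm[cand])] # window start first
    i <- cand[which.max(profile$area_mm2[cand])]
    out$sinus_valsalva <- landmark_at_sample(centerline, i, "sinus_valsalva",
                                             "max CSA within 20 mm distal to the VA junction")
    sv <- profile$arc_length_mm[i]
    sel_j <- profile$arc_length_mm <= sv - rw$stj[1] &
      profile$arc_length_mm >= sv - rw$stj[2] & profile$valid
    if (any(sel_j)) {
      cand <- which(sel_j)
      cand <- cand[order(-profile$arc_length_mm[cand])]
      j <- cand[which.min(profile$area_mm2[cand])]
      out$sinotubular_junction <-
        landmark_at_sample(centerline, j, "sinotubular_junction",
                           "min CSA 5-25 mm beyond the sinus")
    } else {
      out$sinotubular_junction$warning <- "sinotubular window beyond the profile"
    }
  } else {
    out$sinus_valsalva$warning <- "sinus window beyond the profile"
  }
  if (!is.null(annulus_profile) && !is.null(annulus_va_mm)) {
    sel_a <- annulus_profile$arc_length_mm >= annulus_va_mm &
      annulus_profile$arc_length_mm <= annulus_va_mm + rw$annulus &
      annulus_profile$valid
    if (any(sel_a)) {
      cand <- which(sel_a)
      cand <- cand[order(annulus_profile$arc_length_mm[cand])]
      k <- cand[which.min(annulus_profile$area_mm2[cand])]
      lm <- landmark_at_sample(annulus_centerline, k, "annulus",
                               "min CSA within 10 mm proximal to the VA junction (combined LV-aorta line)")
      # report in aortic arc-length coordinates; keep the combined-line
      # position for slicing the combined straightened volume
      lm$arc_length_combined_mm <- annulus_profile$arc_length_mm[k]
      lm$arc_length_mm <- va +
        (annulus_profile$arc_length_mm[k] - annulus_va_mm)
      out$annulus <- lm
    } else {
      out$annulus$warning <- "annulus window beyond the combined profile"
    }
  }
  out
}

#' Extend the centerline into the left ventricle
#'
#' Builds the combined LV-aorta centerline used for the annulus landmark:
#' the medial path is continued from the valve end of the aortic centerline
#' toward the LV blood-pool center of mass, restricted to the union of lumen
#' and LV, for up to `lv_extension_mm`.
#'
#' @param lumen_mask,lv_mask logical 3-D arrays.
#' @param centerline the aortic `centerline` (valve end last).
#' @param vol geometry.
#' @param config an [pipeline_config()].
#' @return list with `centerline` (combined, frames set), `va_mm` (arc length
#'   of the valve end of the aortic line on the combined line), or `NULL`
#'   when the LV is missing/unreachable.
#' @export
lv_extension <- function(lumen_mask, lv_mask, centerline, vol,
                         config = pipeline_config()) {
  if (!any(lv_mask)) return(NULL)
  combined <- lumen_mask | lv_mask
  endv <- centerline$samples[nrow(centerline$samples), ]
  target <- mask_com(lv_mask, vol)
  pts <- try(extract_centerline(combined,
                                list(start = endv, end = target),
                                vol, config), silent = TRUE)
  if (inherits(pts, "try-error")) return(NULL)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  pts <- pts[arc <= config$lv_extension_mm, , drop = FALSE]
  if (nrow(pts) < 2) return(NULL)
  # append the raw extension to the fitted aortic line and refit lightly
  all_pts <- rbind(centerline$samples, pts[-1, , drop = FALSE])
  cl <- resample_polyline(all_pts, centerline$step_mm)
  cl <- compute_frames(cl)
  va_mm <- centerline$total_length_mm
  list(centerline = cl, va_mm = va_mm)
}

#' Partition the centerline into anatomical segments
#'
#' Segment boundaries equal landmark arc lengths exactly. Missing landmarks
#' leave the affected segments flagged unavailable (never silently merged).
#'
#' @param landmarks named list of `aorta_landmark`s (`ventricular_aortic`,
#'   `proximal_arch`, `distal_arch`, `diaphragm`, `renal` as available).
#' @param centerline the `centerline` being partitioned.
#' @param scan_class `"full"`, `"abdominal"` or `"cardiac_two_part"`.
#' @return A data.frame of class `segment_table`: `segment`, `start_mm`,
#'   `end_mm` (increasing arc length), `available`.
#' @export
partition_segments <- function(landmarks, centerline, scan_class) {
  L <- centerline$total_length_mm
  s_of <- function(nm) {
    lm <- landmarks[[nm]]
    if (is.null(lm) || lm$missing) NA_real_ else lm$arc_length_mm
  }
  rows <- if (scan_class == "full") {
    data.frame(
      segment = c("infrarenal", "suprarenal", "descending", "arch", "ascending"),
      start_mm = c(0, s_of("renal"), s_of("diaphragm"), s_of("distal_arch"),
                   s_of("proximal_arch")),
      end_mm = c(s_of("renal"), s_of("diaphragm"), s_of("distal_arch"),
                 s_of("proximal_arch"), s_of("ventricular_aortic")))
  } else if (scan_class == "abdominal") {
    top <- if (!is.na(s_of("diaphragm"))) s_of("diaphragm") else L
    data.frame(
      segment = c("infrarenal", "suprarenal",
                  if (!is.na(s_of("diaphragm"))) "descending"),
      start_mm = c(0, s_of("renal"), if (!is.na(s_of("diaphragm"))) top),
      end_mm = c(s_of("renal"), top, if (!is.na(s_of("diaphragm"))) L))
  } else if (scan_class == "cardiac_two_part") {
    nm <- attr(centerline, "component_name")
    if (identical(nm, "ascending")) {
      data.frame(segment = "ascending", start_mm = 0,
                 end_mm = s_of("ventricular_aortic"))
    } else {
      data.frame(segment = "descending", start_mm = 0, end_mm = L)
    }
  } else {
    data.frame(segment = character(), start_mm = numeric(),
               end_mm = numeric())
  }
  rows$available <- !is.na(rows$start_mm) & !is.na(rows$end_mm) &
    rows$end_mm > rows$start_mm
  class(rows) <- c("segment_table", "data.frame")
  rows
}
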