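# End-to-end orchestration: classify -> refine -> endpoints -> centerline ->
# frames -> CPR -> landmarks -> segments -> biomarkers -> report. Degraded
# inputs produce partial reports with warnings; rejection is a valid outcome.

#' Analyze one scan
#'
#' Runs the full post-segmentation pipeline on an image/label pair. The scan
#' class is determined automatically (or forced); incomplete scans yield a
#' partial set of measurements with warnings about missing values, and
#' non-contrast or empty-lumen scans are rejected with machine-readable
#' reasons.
#'
#' @param image an [image_volume()] or a path readable by [read_image()].
#' @param labels an [label_volume()] or a path readable by [read_labels()].
#' @param config an [pipeline_config()].
#' @param out_dir optional directory; when given, [write_report()] is called.
#' @param scan_class `"auto"` (default) or one of `"full"`, `"abdominal"`,
#'   `"cardiac_two_part"` to override the classifier.
#' @return An `aorta_report`.
#' @export
analyze <- function(image, labels, config = pipeline_config(),
                    out_dir = NULL, scan_class = "auto") {
  if (is.character(image)) image <- read_image(image)
  if (is.character(labels)) labels <- read_labels(labels, reference = image)
  warns <- character()
  note <- function(msg) warns <<- c(warns, msg)

  aorta_mask <- structure_mask(labels, "aorta")
  cls <- classify_scan(aorta_mask, labels, image, config)
  if (scan_class != "auto") {
    cls$reasons <- c(cls$reasons,
                     sprintf("class forced to %s (auto: %s)", scan_class,
                             cls$class))
    cls$class <- scan_class
  }

  finish <- function(status, ...) {
    rep <- assemble_report(classification = cls, config = config,
                           warnings = warns, status = status, ...)
    if (!is.null(out_dir)) write_report(rep, out_dir)
    rep
  }
  if (cls$class == "rejected") {
    note(paste("scan rejected:", paste(cls$reasons, collapse = "; ")))
    return(finish("rejected"))
  }

  lum <- tryCatch(suppressWarnings(refine_aorta(aorta_mask, image, config)),
                  error = function(e) e)
  if (inherits(lum, "error")) {
    cls$class <- "rejected"
    cls$reasons <- c(cls$reasons, conditionMessage(lum))
    note(paste("lumen refinement failed:", conditionMessage(lum)))
    return(finish("rejected"))
  }
  if (lum$empty) {
    cls$class <- "rejected"
    cls$reasons <- c(cls$reasons,
                     "empty lumen after refinement (probable non-contrast scan)")
    note("empty lumen after refinement")
    return(finish("rejected", lumen = lum))
  }
  # QC on the raw thresholded lumen: the cleanup morphology would mask the
  # porosity that indicates a non-contrast or artifact-ridden acquisition
  svr <- surface_to_volume_check(lum$thresholded_mask, image$spacing,
                                 config$surface_volume_threshold)
  qc <- list(surface_to_volume_per_mm = svr$ratio_per_mm,
             surface_to_volume_flag = svr$flag)
  if (svr$flag) {
    cls$class <- "rejected"
    cls$reasons <- c(cls$reasons,
                     sprintf("surface-to-volume ratio %.2f/mm exceeds %.2f/mm (porous lumen, probable non-contrast scan)",
                             svr$ratio_per_mm, config$surface_volume_threshold))
    note("porous lumen surface")
    return(finish("rejected", lumen = lum, qc = qc))
  }
  if (cls$class == "partial") {
    note("partial field of view: no centerline analysis attempted")
    return(finish("degraded", lumen = lum, qc = qc))
  }

  eps <- tryCatch(determine_endpoints(lum$lumen_mask, labels, cls$class,
                                      image, config),
                  error = function(e) e)
  if (inherits(eps, "error")) {
    note(paste("endpoint determination failed:", conditionMessage(eps)))
    return(finish("degraded", lumen = lum, qc = qc))
  }

  dil <- config$artery_dilation_mm
  lv <- structure_mask(labels, "lv_blood")
  rv <- structure_mask(labels, "rv_blood")
  liver <- structure_mask(labels, "liver")
  kl <- structure_mask(labels, "kidney_left")
  kr <- structure_mask(labels, "kidney_right")

  all_landmarks <- list()
  all_meas <- list()
  all_torts <- list()
  all_segments <- list()
  main_csa <- NULL

  for (pair in eps) {
    line_mask <- if (!is.null(pair$component)) pair$component else lum$lumen_mask
    cl <- tryCatch(centerline_pipeline(line_mask, pair, image, config),
                   error = function(e) e)
    if (inherits(cl, "error")) {
      note(sprintf("centerline failed (%s): %s", pair$name,
                   conditionMessage(cl)))
      next
    }
    attr(cl, "component_name") <- pair$name
    st <- straighten(image, line_mask, cl, config)
    prof <- csa_profile(st)
    if (is.null(main_csa) || cl$total_length_mm >
        attr(main_csa, "line_length") %||% 0) {
      main_csa <- prof
      attr(main_csa, "line_length") <- cl$total_length_mm
    }

    lms <- list()
    root <- NULL
    ann_st <- NULL
    if (cls$class %in% c("full", "abdominal")) {
      i_bif <- nearest_sample(cl, pair$bifurcation %||% pair$start)
      lms$bifurcation <- landmark_at_sample(cl, i_bif, "bifurcation",
                                            "iliac bifurcation")
      lms$renal <- renal_landmark(kl, kr, cl, image)
      lms$diaphragm <- diaphragm_landmark(rv, liver, cl, image)
      if (lms$diaphragm$missing)
        note("diaphragm landmark missing: descending/abdominal boundary falls back to the scan boundary")
    }
    if (cls$class == "full") {
      lms$ventricular_aortic <- overlap_landmark(lum$lumen_mask, lv, cl,
                                                 image, dil,
                                                 "ventricular_aortic")
      arch <- arch_landmarks(lum$lumen_mask, labels, cl, image, config)
      lms$proximal_arch <- arch$proximal_arch
      lms$distal_arch <- arch$distal_arch
      lms$left_subclavian <- arch$left_subclavian
      lms$left_common_carotid <- arch$left_common_carotid
    }
    if (cls$class == "cardiac_two_part" && pair$name == "ascending") {
      lms$ventricular_aortic <- overlap_landmark(line_mask, lv, cl, image,
                                                 dil, "ventricular_aortic")
    }

    needs_root <- !is.null(lms$ventricular_aortic) &&
      !lms$ventricular_aortic$missing
    if (needs_root) {
      ext <- lv_extension(line_mask, lv, cl, image, config)
      ann_prof <- NULL; ann_cl <- NULL; ann_va <- NULL
      if (!is.null(ext)) {
        # straighten only the root neighborhood of the combined line; the
        # annulus window is anchored at the ventricular-aortic landmark
        va_arc <- lms$ventricular_aortic$arc_length_mm
        keep <- ext$centerline$arc_length >= va_arc - 5
        sub <- resample_polyline(ext$centerline$samples[keep, , drop = FALSE],
                                 ext$centerline$step_mm)
        sub <- compute_frames(sub)
        ann_st <- straighten(image, line_mask | lv, sub, config)
        ann_prof <- csa_profile(ann_st)
        ann_cl <- sub
        ann_va <- va_arc - min(ext$centerline$arc_length[keep])
      } else {
        note("combined LV-aorta centerline unavailable: annulus landmark missing")
      }
      root <- root_landmarks(prof, lms$ventricular_aortic, cl,
                             annulus_profile = ann_prof,
                             annulus_centerline = ann_cl,
                             annulus_va_mm = ann_va, config = config)
      lms <- c(lms, root)
    }

    for (lm in lms)
      if (lm$missing) note(sprintf("landmark %s missing: %s", lm$name,
                                   lm$warning))
      else if (!is.null(lm$warning)) note(lm$warning)

    segs <- partition_segments(lms, cl, cls$class)
    if (any(!segs$available))
      note(paste("segments unavailable:",
                 paste(segs$segment[!segs$available], collapse = ", ")))
    meas <- measure_segments(prof, st, segs, root = root,
                             annulus_straightened = ann_st, config = config)

    if (cls$class == "full") {
      if (!lms$distal_arch$missing && !lms$diaphragm$missing)
        all_torts$descending <- tortuosity(cl, lms$distal_arch,
                                           lms$diaphragm, "descending")
      else note("descending tortuosity unavailable (missing landmarks)")
      if (!lms$ventricular_aortic$missing)
        all_torts$full_aortic <- tortuosity(cl, lms$bifurcation,
                                            lms$ventricular_aortic,
                                            "full_aortic")
      else note("full aortic tortuosity unavailable (missing landmarks)")
    }

    all_landmarks <- c(all_landmarks, lms)
    all_segments[[length(all_segments) + 1]] <- segs
    all_meas[[length(all_meas) + 1]] <- meas
  }

  if (cls$class == "abdominal")
    note("restricted abdominal field of view: thoracic segments, root landmarks and tortuosity unavailable")
  if (cls$class == "cardiac_two_part")
    note("two-part cardiac field of view: abdominal segments and tortuosity unavailable")
  segments <- if (length(all_segments)) do.call(rbind, all_segments)
  measurements <- if (length(all_meas)) do.call(rbind, all_meas)
  complete <- switch(cls$class,
                     full = !is.null(measurements) &&
                       all(c("infrarenal", "suprarenal", "descending", "arch",
                             "ascending", "sinus_valsalva",
                             "sinotubular_junction", "annulus") %in%
                             measurements$name),
                     TRUE)
  status <- if (length(warns) || !complete) "degraded" else "ok"
  finish(status, lumen = lum, landmarks = all_landmarks,
         segments = segments, measurements = measurements,
         tortuosity = all_torts, qc = qc, csa = main_csa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Batch analysis of a directory
#'
#' Processes every `<case>_image.nii[.gz]` / `<case>_labels.nii[.gz]` (or
#' `.nrrd`) pair found in `dir`. Cases run independently (optionally in
#' parallel); one failing case never aborts the batch.
#'
#' @param dir directory of paired image/label files.
#' @param config an [pipeline_config()].
#' @param out_dir output directory; one subdirectory per case.
#' @param n_workers number of worker processes (forked; results are
#'   identical for any worker count).
#' @return A data.frame manifest (class `run_manifest`): `case`, `status`,
#'   `reasons`, `seconds`.
#' @export
analyze_batch <- function(dir, config = pipeline_config(), out_dir = NULL,
                          n_workers = 1) {
  imgs <- list.files(dir, pattern = "_image\\.(nii|nii\\.gz|nrrd)$",
                     full.names = TRUE)
  cases <- sub("_image\\.(nii|nii\\.gz|nrrd)$", "", basename(imgs))
  if (!length(cases)) stop("no cases found in ", dir)
  run_one <- function(i) {
    # workers only compute; report files (including graphics devices, which
    # are not fork-safe) are written by the parent afterwards
    t0 <- proc.time()[["elapsed"]]
    rep <- tryCatch(analyze(imgs[i], sub("_image\\.", "_labels.", imgs[i]),
                            config),
                    error = function(e) e)
    list(rep = rep, seconds = proc.time()[["elapsed"]] - t0)
  }
  out <- if (n_workers > 1) {
    gc(FALSE) # shrink the heap before forking
    parallel::mclapply(seq_along(cases), run_one, mc.cores = n_workers)
  } else {
    lapply(seq_along(cases), run_one)
  }
  # a forked worker that dies (e.g. under memory pressure) delivers NULL;
  # recompute those cases serially so the batch result never depends on it
  for (i in seq_along(out))
    if (is.null(out[[i]]) || is.null(out[[i]]$rep)) out[[i]] <- run_one(i)
  rows <- lapply(seq_along(cases), function(i) {
    rep <- out[[i]]$rep
    if (inherits(rep, "error"))
      return(data.frame(case = cases[i], status = "failed",
                        reasons = conditionMessage(rep),
                        seconds = out[[i]]$seconds))
    if (!is.null(out_dir)) write_report(rep, file.path(out_dir, cases[i]))
    data.frame(case = cases[i], status = rep$status,
               reasons = paste(rep$classification$reasons, collapse = "; "),
               seconds = out[[i]]$seconds)
  })
  manifest <- do.call(rbind, rows)
  class(manifest) <- c("run_manifest", "data.frame")
  manifest
}
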