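# Failure-case safeguards: scan field-of-view classification, lumen
# surface-to-volume screening for non-contrast/porous segmentations, and the
# per-slice ellipse aspect check (in biomarkers.R).

#' Classify the scan field of view
#'
#' Counts the 26-connected components of the aorta label (components smaller
#' than `min_component_mm3` ignored). Two components indicate a two-part
#' cardiac scan (ascending + descending cut by the field of view); a single
#' component reaching both the arch-branch region and the iliac region is a
#' full-aorta scan; a single component with kidneys present but no arch
#' branches is abdominal; anything else is partial. An empty aorta label
#' rejects the scan.
#'
#' @param aorta_mask logical 3-D array.
#' @param labels an [label_volume()].
#' @param vol the [image_volume()] (geometry).
#' @param config an [pipeline_config()].
#' @return list of class `scan_classification`: `class` (full | abdominal |
#'   cardiac_two_part | partial | rejected), `component_count`, `reasons`.
#' @export
classify_scan <- function(aorta_mask, labels, vol,
                          config = pipeline_config()) {
  reasons <- character()
  if (!any(aorta_mask))
    return(structure(list(class = "rejected", component_count = 0L,
                          reasons = "no aorta"),
                     class = "scan_classification"))
  big <- drop_small_components(aorta_mask, vol$spacing,
                               config$min_component_mm3)
  lab <- connected_components(big)
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0)
    return(structure(list(class = "rejected", component_count = 0L,
                          reasons = "aorta below minimum volume"),
                     class = "scan_classification"))
  dil <- dilate_mask(big, config$artery_dilation_mm, vol$spacing)
  touches <- function(nm) any(dil & structure_mask(labels, nm))
  has_arch <- touches("brachiocephalic_trunk") || touches("left_subclavian") ||
    touches("left_common_carotid")
  has_iliac <- touches("iliac_left") && touches("iliac_right")
  has_kidneys <- any(structure_mask(labels, "kidney_left")) &&
    any(structure_mask(labels, "kidney_right"))
  cls <- if (ncomp >= 2) {
    if (ncomp > 2) reasons <- c(reasons, sprintf("%d components", ncomp))
    "cardiac_two_part"
  } else if (has_arch && has_iliac) {
    "full"
  } else if (has_iliac && has_kidneys && !has_arch) {
    "abdominal"
  } else {
    reasons <- c(reasons, "single component without full or abdominal coverage")
    "partial"
  }
  structure(list(class = cls, component_count = ncomp, reasons = reasons),
            class = "scan_classification")
}

#' @export
print.scan_classification <- function(x, ...) {
  cat(sprintf("<scan> %s (%d component%s)%s\n", x$class, x$component_count,
              if (x$component_count == 1) "" else "s",
              if (length(x$reasons)) paste0(": ", paste(x$reasons, collapse = "; "))
              else ""))
  invisible(x)
}

#' Surface-to-volume check of the refined lumen
#'
#' A high surface-to-volume ratio indicates a rough or porous lumen surface,
#' typical of non-contrast imaging or acquisition artifacts. The surface
#' area is estimated with the co-area formula: the integral of the gradient
#' magnitude of the mask indicator (lightly smoothed, sigma = 0.3 voxel, to
#' regularize the discrete gradient), which approximates the area of the
#' iso-surface while retaining the porosity signal that heavier smoothing
#' would average away; the volume is the voxel count times the voxel volume.
#'
#' @param lumen_mask logical 3-D array.
#' @param spacing voxel size in mm.
#' @param threshold flag ratio above this (1/mm).
#' @return list with `ratio_per_mm`, `surface_mm2`, `volume_mm3`, `flag`.
#' @export
surface_to_volume_check <- function(lumen_mask, spacing, threshold = 0.5) {
  if (!any(lumen_mask)) stop("empty lumen mask")
  g <- gaussian_smooth(array(as.numeric(lumen_mask), dim(lumen_mask)),
                       c(0.3, 0.3, 0.3))
  d <- dim(g)
  grad2 <- array(0, d)
  for (ax in 1:3) {
    ip <- pmin(seq_len(d[ax]) + 1L, d[ax])
    im <- pmax(seq_len(d[ax]) - 1L, 1L)
    df <- (slice_index(g, ax, ip) - slice_index(g, ax, im)) / (2 * spacing[ax])
    grad2 <- grad2 + df^2
  }
  surface <- sum(sqrt(grad2)) * prod(spacing)
  volume <- sum(lumen_mask) * prod(spacing)
  ratio <- surface / volume
  list(ratio_per_mm = ratio, surface_mm2 = surface, volume_mm3 = volume,
       flag = ratio > threshold)
}
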