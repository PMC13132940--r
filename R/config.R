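#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis with its default. The
#' defaults for the lumen/calcification thresholds and the landmark windows
#' follow the published protocol; purely numerical knobs (CPR resolution,
#' medial-path epsilon, morphology radius) are this package's own choices and
#' are documented in the methods vignette.
#'
#' @param alpha unitless weighting of the lumen HU spread in the adaptive
#'   calcification threshold `max(min_hu, mu + alpha * sigma)` (default 3).
#' @param min_hu minimum calcification threshold in HU (default 400).
#' @param lumen_band multiples of sigma defining the lumen HU band
#'   `[mu - band[1]*sigma, mu + band[2]*sigma]` (default `c(5, 3)`).
#' @param skeleton_dilation_mm dilation of the skeleton before HU sampling
#'   (default 1 mm).
#' @param artery_dilation_mm dilation used for organ/artery overlap landmarks
#'   (default 5 mm).
#' @param distal_arch_offset_mm arc-length shift from the left-subclavian
#'   projection toward the descending aorta (default 20 mm).
#' @param root_windows_mm list with elements `sinus` (distal window after the
#'   ventricular-aortic landmark, default 20), `stj` (window beyond the sinus,
#'   default `c(5, 25)`) and `annulus` (proximal window, default 10), all mm.
#' @param cpr_slice_step_mm arc-length step between straightened slices.
#' @param cpr_inplane_res_mm in-plane resolution of straightened slices.
#' @param cpr_halfwidth_mm half width of the straightened field of view.
#' @param aspect_ratio_threshold best-fit-ellipse aspect ratio above which a
#'   diameter slice is discarded (default 2.5).
#' @param surface_volume_threshold lumen surface-to-volume ratio (1/mm) above
#'   which the scan is rejected as non-contrast/porous (default 0.5).
#' @param medial_eps_mm epsilon in the medial path edge cost (default 0.1).
#' @param morph_radius_mm structuring-element radius for the opening/closing
#'   applied after lumen thresholding; `NULL` means one in-plane voxel.
#' @param spline_df_per_mm degrees of freedom per mm of vessel for the
#'   centerline smoothing spline (default 0.3: anatomy above ~7 mm
#'   wavelength is preserved; voxel-scale staircase is suppressed by the
#'   spline and the subsequent cross-sectional recentering pass).
#' @param centerline_extend_mm allowance for extending the fitted centerline
#'   along its end tangents to the lumen surface (default 25); ends farther
#'   from the surface are genuine interior points and are not extended.
#' @param lv_extension_mm length of the combined left-ventricle extension of
#'   the centerline used for the annulus landmark (default 30).
#' @param min_component_mm3 connected components smaller than this are ignored
#'   by the scan classifier (default 1000 = 1 cm^3).
#' @param rng_seed optional integer seed recorded in reports.
#' @return A list of class `aortax_config`.
#' @export
pipeline_config <- function(alpha = 3,
                            min_hu = 400,
                            lumen_band = c(5, 3),
                            skeleton_dilation_mm = 1,
                            artery_dilation_mm = 5,
                            distal_arch_offset_mm = 20,
                            root_windows_mm = list(sinus = 20,
                                                   stj = c(5, 25),
                                                   annulus = 10),
                            cpr_slice_step_mm = 1,
                            cpr_inplane_res_mm = 0.5,
                            cpr_halfwidth_mm = 40,
                            aspect_ratio_threshold = 2.5,
                            surface_volume_threshold = 0.5,
                            medial_eps_mm = 0.1,
                            morph_radius_mm = NULL,
                            spline_df_per_mm = 0.3,
                            centerline_extend_mm = 25,
                            lv_extension_mm = 30,
                            min_component_mm3 = 1000,
                            rng_seed = NULL) {
  cfg <- list(alpha = alpha, min_hu = min_hu, lumen_band = lumen_band,
              skeleton_dilation_mm = skeleton_dilation_mm,
              artery_dilation_mm = artery_dilation_mm,
              distal_arch_offset_mm = distal_arch_offset_mm,
              root_windows_mm = root_windows_mm,
              cpr_slice_step_mm = cpr_slice_step_mm,
              cpr_inplane_res_mm = cpr_inplane_res_mm,
              cpr_halfwidth_mm = cpr_halfwidth_mm,
              aspect_ratio_threshold = aspect_ratio_threshold,
              surface_volume_threshold = surface_volume_threshold,
              medial_eps_mm = medial_eps_mm,
              morph_radius_mm = morph_radius_mm,
              spline_df_per_mm = spline_df_per_mm,
              centerline_extend_mm = centerline_extend_mm,
              lv_extension_mm = lv_extension_mm,
              min_component_mm3 = min_component_mm3,
              rng_seed = rng_seed)
  validate_config(cfg)
  structure(cfg, class = "aortax_config")
}

validate_config <- function(cfg) {
  dists <- c("skeleton_dilation_mm", "artery_dilation_mm",
             "distal_arch_offset_mm", "cpr_slice_step_mm",
             "cpr_inplane_res_mm", "cpr_halfwidth_mm", "medial_eps_mm",
             "centerline_extend_mm", "lv_extension_mm")
  for (nm in dists) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("config field '", nm, "' must be a positive number")
  }
  if (!is.numeric(cfg$min_hu) || length(cfg$min_hu) != 1 || cfg$min_hu < 0)
    stop("config field 'min_hu' must be a non-negative number")
  if (!is.numeric(cfg$alpha) || length(cfg$alpha) != 1 || !is.finite(cfg$alpha))
    stop("config field 'alpha' must be numeric")
  if (length(cfg$lumen_band) != 2 || any(cfg$lumen_band < 0))
    stop("config field 'lumen_band' must be two non-negative multiples of sigma")
  rw <- cfg$root_windows_mm
  if (rw$sinus <= 0 || rw$annulus <= 0 || length(rw$stj) != 2 ||
      any(rw$stj < 0) || rw$stj[2] <= rw$stj[1])
    stop("invalid root_windows_mm")
  invisible(TRUE)
}

#' Load a configuration, optionally overridden from a JSON file
#'
#' Unspecified keys fall back to the defaults of [pipeline_config()].
#'
#' @param path optional path to a JSON file of overrides; `NULL` gives pure
#'   defaults.
#' @param ... further overrides applied after the file.
#' @return An `aortax_config`.
#' @export
load_config <- function(path = NULL, ...) {
  over <- list(...)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_over <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(file_over), names(formals(pipeline_config)))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    file_over[names(over)] <- over
    over <- file_over
  }
  do.call(pipeline_config, over)
}

#' @export
print.aortax_config <- function(x, ...) {
  cat("<aortax_config>\n")
  cat(sprintf("  calcification: alpha = %g, min_hu = %g HU\n", x$alpha, x$min_hu))
  cat(sprintf("  lumen band: [mu - %g sigma, mu + %g sigma]\n",
              x$lumen_band[1], x$lumen_band[2]))
  cat(sprintf("  CPR: step %g mm, in-plane %g mm, half-width %g mm\n",
              x$cpr_slice_step_mm, x$cpr_inplane_res_mm, x$cpr_halfwidth_mm))
  cat(sprintf("  QC: aspect ratio <= %g, surface/volume <= %g 1/mm\n",
              x$aspect_ratio_threshold, x$surface_volume_threshold))
  invisible(x)
}
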