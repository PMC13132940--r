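# Lumen/calcification sub-segmentation of the aorta label. The upstream
# segmentation includes the wall, calcified plaque and any dilation; clinical
# diameter protocols measure the contrast-enhanced lumen only, so the label
# is re-split using HU statistics sampled along the skeleton.

#' Skeleton-sampled lumen HU statistics
#'
#' Thins the aorta mask to a curve skeleton, dilates it by
#' `skeleton_dilation_mm` (1 mm default) to obtain voxels that are pure lumen
#' with high confidence, and summarizes their HU values.
#'
#' @param aorta_mask logical 3-D array (the aorta label).
#' @param image the corresponding [image_volume()].
#' @param config an [pipeline_config()].
#' @return A list of class `lumen_stats` with `mu_hu`, `sigma_hu`,
#'   `n_samples`, and the dilated skeleton mask used for sampling.
#' @export
skeleton_lumen_stats <- function(aorta_mask, image, config = pipeline_config()) {
  if (!any(aorta_mask)) stop("empty aorta mask")
  # anchor the distance-transform ridge (local maxima of the distance to the
  # boundary, away from thin end regions) so the skeleton stays on the
  # vessel core and its samples are pure lumen with high confidence
  dtb <- distance_to_boundary(aorta_mask, image$spacing)
  ridge <- aorta_mask & dtb >= max_filter3(dtb) - 1e-9 &
    dtb >= 0.5 * max(dtb)
  skel <- skeletonize(aorta_mask, anchor = ridge)
  if (sum(skel) < 10) stop("degenerate aorta geometry: skeleton of < 10 voxels")
  samp <- dilate_mask(skel, config$skeleton_dilation_mm, image$spacing) &
    aorta_mask
  hu <- image$voxels[samp]
  structure(list(mu_hu = mean(hu), sigma_hu = stats::sd(hu),
                 n_samples = length(hu), skeleton = skel,
                 sample_mask = samp),
            class = "lumen_stats")
}

#' @export
print.lumen_stats <- function(x, ...) {
  cat(sprintf("<lumen_stats> mu = %.1f HU, sigma = %.1f HU (n = %d)\n",
              x$mu_hu, x$sigma_hu, x$n_samples))
  invisible(x)
}

#' Refine the aorta label to the contrast-enhanced lumen
#'
#' Keeps aorta voxels whose HU lies in `[mu - 5 sigma, mu + 3 sigma]`
#' (excluding the darker wall below and calcifications above), retains the
#' connected components that touch the dilated skeleton, and applies
#' morphological opening then closing. A zero-sigma band is widened to
#' +/- 1 HU so constant-intensity inputs keep a non-empty band.
#'
#' @param aorta_mask logical 3-D array.
#' @param image the [image_volume()].
#' @param stats a [skeleton_lumen_stats()] result.
#' @param config an [pipeline_config()].
#' @return Logical lumen mask with attributes `band` (the applied HU
#'   interval), `empty` (TRUE when thresholding left nothing: probable
#'   non-contrast scan) and `n_band_violations` (voxels added by closing
#'   whose HU falls outside the band).
#' @export
refine_lumen <- function(aorta_mask, image, stats,
                         config = pipeline_config()) {
  sig <- max(stats$sigma_hu, 0)
  lo <- stats$mu_hu - config$lumen_band[1] * sig
  hi <- stats$mu_hu + config$lumen_band[2] * sig
  if (sig == 0) { lo <- lo - 1; hi <- hi + 1 }
  band <- c(lo, hi)
  in_band <- aorta_mask & image$voxels >= lo & image$voxels <= hi
  out <- in_band
  if (any(out)) {
    lab <- connected_components(out)
    keep <- sort(unique(lab[stats$sample_mask & out]))
    keep <- keep[keep > 0]
    out <- array(lab %in% keep, dim(out))
  }
  r <- config$morph_radius_mm
  if (is.null(r)) r <- max(image$spacing[1:2])
  out <- open_mask(out, r, image$spacing)
  out <- close_mask(out, r, image$spacing)
  out <- fill_holes(out) # the post-processing removes interior holes
  out <- out & aorta_mask
  # closing and hole filling may only re-admit sub-threshold voxels: voxels
  # at or above the adaptive calcification threshold are never lumen
  thr <- calcification_threshold(stats$mu_hu, sig, config$alpha,
                                 config$min_hu)
  out <- out & image$voxels < thr
  viol <- sum(out & !(image$voxels >= lo & image$voxels <= hi))
  empty <- !any(out)
  if (empty)
    warning("empty lumen after refinement: probable non-contrast scan")
  attr(out, "band") <- band
  attr(out, "empty") <- empty
  attr(out, "n_band_violations") <- viol
  out
}

#' Extract calcifications with the adaptive HU threshold
#'
#' Voxels of the aorta label outside the refined lumen with HU at or above
#' `max(min_hu, mu + alpha * sigma)` are classified as calcified plaque. The
#' calcification ratio is `100 * |calc| / (|lumen| + |calc|)` (the
#' denominator is a package choice, see the methods vignette).
#'
#' @param aorta_mask,lumen_mask logical 3-D arrays.
#' @param image the [image_volume()].
#' @param stats a [skeleton_lumen_stats()] result.
#' @param config an [pipeline_config()].
#' @return list with `calcification_mask`, `calcification_ratio` (percent)
#'   and `calc_threshold` (HU).
#' @export
extract_calcifications <- function(aorta_mask, lumen_mask, image, stats,
                                   config = pipeline_config()) {
  thr <- calcification_threshold(stats$mu_hu, stats$sigma_hu,
                                 config$alpha, config$min_hu)
  calc <- aorta_mask & !lumen_mask & image$voxels >= thr
  nl <- sum(lumen_mask); nc <- sum(calc)
  ratio <- if (nl + nc > 0) 100 * nc / (nl + nc) else 0
  list(calcification_mask = calc, calcification_ratio = ratio,
       calc_threshold = thr)
}

#' Adaptive calcification threshold
#'
#' @param mu_hu,sigma_hu skeleton-sampled lumen HU statistics.
#' @param alpha weighting factor (default 3).
#' @param min_hu minimum threshold in HU (default 400).
#' @return `max(min_hu, mu_hu + alpha * sigma_hu)` in HU.
#' @export
calcification_threshold <- function(mu_hu, sigma_hu, alpha = 3, min_hu = 400) {
  max(min_hu, mu_hu + alpha * sigma_hu)
}

#' Full lumen/calcification refinement of an aorta label
#'
#' Convenience wrapper chaining [skeleton_lumen_stats()], [refine_lumen()]
#' and [extract_calcifications()].
#'
#' @inheritParams refine_lumen
#' @return A list of class `lumen_result`: `lumen_mask`,
#'   `calcification_mask`, `stats`, `band`, `calc_threshold`,
#'   `calcification_ratio`, `empty`.
#' @export
refine_aorta <- function(aorta_mask, image, config = pipeline_config()) {
  stats <- skeleton_lumen_stats(aorta_mask, image, config)
  lumen <- refine_lumen(aorta_mask, image, stats, config)
  calc <- extract_calcifications(aorta_mask, lumen, image, stats, config)
  band <- attr(lumen, "band")
  structure(list(lumen_mask = lumen,
                 # raw thresholded lumen, before morphological cleanup: used
                 # by the surface-to-volume QC, where a porous surface is the
                 # evidence of a non-contrast or artifact-ridden scan
                 thresholded_mask = aorta_mask & image$voxels >= band[1] &
                   image$voxels <= band[2],
                 calcification_mask = calc$calcification_mask,
                 stats = stats,
                 band = attr(lumen, "band"),
                 calc_threshold = calc$calc_threshold,
                 calcification_ratio = calc$calcification_ratio,
                 empty = attr(lumen, "empty")),
            class = "lumen_result")
}

#' @export
print.lumen_result <- function(x, ...) {
  cat(sprintf("<lumen_result> lumen %d vox, calcification %d vox (%.2f%%), band [%.0f, %.0f] HU, threshold %.0f HU\n",
              sum(x$lumen_mask), sum(x$calcification_mask),
              x$calcification_ratio, x$band[1], x$band[2], x$calc_threshold))
  invisible(x)
}

#' Parameter sweep for the calcification threshold
#'
#' Re-runs calcification extraction over a grid of `alpha` and `min_hu`
#' values on one or several scans, reporting the mean and spread of the
#' calcification ratio and the number of refinement failures (scans with an
#' empty lumen after thresholding).
#'
#' @param cases list of `list(aorta_mask=, image=)` pairs (a single pair is
#'   also accepted).
#' @param alphas,min_hus numeric vectors of parameter values.
#' @param config base configuration.
#' @return data.frame with one row per (alpha, min_hu) combination:
#'   `ratio_mean`, `ratio_sd`, `n_failed`.
#' @export
sweep_calcification_params <- function(cases, alphas = c(1, 3, 5),
                                       min_hus = c(200, 400, 600),
                                       config = pipeline_config()) {
  if (!is.null(cases$aorta_mask)) cases <- list(cases)
  # stats and lumen do not depend on alpha/min_hu: compute once per case
  prep <- lapply(cases, function(cs) {
    st <- try(skeleton_lumen_stats(cs$aorta_mask, cs$image, config),
              silent = TRUE)
    if (inherits(st, "try-error")) return(list(failed = TRUE))
    lum <- suppressWarnings(refine_lumen(cs$aorta_mask, cs$image, st, config))
    list(failed = attr(lum, "empty"), stats = st, lumen = lum, case = cs)
  })
  grid <- expand.grid(alpha = alphas, min_hu = min_hus)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$alpha <- grid$alpha[i]
    cfg$min_hu <- grid$min_hu[i]
    ratios <- vapply(prep, function(p) {
      if (p$failed) return(NA_real_)
      extract_calcifications(p$case$aorta_mask, p$lumen, p$case$image,
                             p$stats, cfg)$calcification_ratio
    }, numeric(1))
    data.frame(alpha = grid$alpha[i], min_hu = grid$min_hu[i],
               ratio_mean = mean(ratios, na.rm = TRUE),
               ratio_sd = if (sum(!is.na(ratios)) > 1)
                 stats::sd(ratios, na.rm = TRUE) else NA_real_,
               n_failed = sum(vapply(prep, `[[`, logical(1), "failed")))
  })
  do.call(rbind, rows)
}
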