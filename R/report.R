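# Report assembly and serialization: JSON document, CSV biomarker/landmark
# tables, and a summary figure (cross-sectional area along the centerline
# with measurement markers, plus a montage of the measured slices).

landmark_table <- function(landmarks) {
  if (!length(landmarks))
    return(data.frame(name = character(), arc_length_mm = numeric(),
                      x_mm = numeric(), y_mm = numeric(), z_mm = numeric(),
                      missing = logical(), provenance = character()))
  do.call(rbind, lapply(landmarks, function(lm) {
    data.frame(name = lm$name,
               arc_length_mm = if (lm$missing) NA_real_ else lm$arc_length_mm,
               x_mm = if (lm$missing) NA_real_ else lm$point[1],
               y_mm = if (lm$missing) NA_real_ else lm$point[2],
               z_mm = if (lm$missing) NA_real_ else lm$point[3],
               missing = lm$missing,
               provenance = if (lm$missing) lm$warning else lm$provenance)
  }))
}

#' Assemble the analysis report
#'
#' Collects classification, lumen statistics, landmarks, segments,
#' measurements, tortuosity, QC results and accumulated warnings into a
#' single document. Warnings are never dropped; missing landmarks and
#' measurements are listed explicitly.
#'
#' @param classification a [classify_scan()] result.
#' @param config the configuration used (snapshot embedded verbatim).
#' @param lumen a [refine_aorta()] result or `NULL`.
#' @param landmarks named list of `aorta_landmark`s.
#' @param segments a [partition_segments()] table or `NULL`.
#' @param measurements a [measure_segments()] table or `NULL`.
#' @param tortuosity list of `tortuosity_result`s.
#' @param qc list of QC results (surface-to-volume etc.).
#' @param warnings character vector.
#' @param status one of `"ok"`, `"degraded"`, `"rejected"`.
#' @param csa optional [csa_profile()] kept for plotting.
#' @return An object of class `aorta_report`.
#' @export
assemble_report <- function(classification, config, lumen = NULL,
                            landmarks = list(), segments = NULL,
                            measurements = NULL, tortuosity = list(),
                            qc = list(), warnings = character(),
                            status = "ok", csa = NULL) {
  structure(list(
    status = status,
    classification = classification,
    config = config,
    software = list(package = "aortax",
                    version = as.character(utils::packageVersion("aortax"))),
    lumen = if (!is.null(lumen)) list(
      mu_hu = lumen$stats$mu_hu, sigma_hu = lumen$stats$sigma_hu,
      n_samples = lumen$stats$n_samples,
      band_hu = lumen$band, calc_threshold_hu = lumen$calc_threshold,
      calcification_ratio_percent = lumen$calcification_ratio),
    landmarks = landmark_table(landmarks),
    segments = segments,
    measurements = measurements,
    tortuosity = tortuosity,
    qc = qc,
    warnings = warnings,
    csa = csa), class = "aorta_report")
}

#' @export
print.aorta_report <- function(x, ...) {
  cat(sprintf("<aorta_report> status: %s, scan class: %s\n", x$status,
              x$classification$class))
  if (!is.null(x$lumen))
    cat(sprintf("  lumen: mu = %.0f HU, sigma = %.0f HU, calcification %.2f%%\n",
                x$lumen$mu_hu, x$lumen$sigma_hu,
                x$lumen$calcification_ratio_percent))
  if (!is.null(x$measurements) && nrow(x$measurements)) {
    cat("  diameters (mm):\n")
    for (i in seq_len(nrow(x$measurements)))
      cat(sprintf("    %-22s %6.1f  (CSA %7.1f mm2 at %5.1f mm)%s\n",
                  x$measurements$name[i], x$measurements$max_diameter_mm[i],
                  x$measurements$csa_mm2[i], x$measurements$arc_length_mm[i],
                  if (x$measurements$qc_pass[i]) "" else " [QC fail]"))
  }
  for (ti in x$tortuosity)
    cat(sprintf("  tortuosity %-12s %.3f (%.1f / %.1f mm)\n", ti$name,
                ti$index, ti$centerline_length_mm, ti$geometric_length_mm))
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("    -", w, "\n")
  }
  invisible(x)
}

report_to_json_list <- function(report) {
  list(
    status = report$status,
    classification = unclass(report$classification),
    software = report$software,
    config = unclass(report$config),
    lumen = report$lumen,
    landmarks = report$landmarks,
    segments = if (!is.null(report$segments)) as.data.frame(report$segments),
    measurements = report$measurements,
    tortuosity = lapply(report$tortuosity, unclass),
    qc = report$qc,
    warnings = as.list(report$warnings))
}

#' Write a report to disk
#'
#' Writes `report.json` (stable schema: status, classification, config,
#' lumen, landmarks, segments, measurements, tortuosity, qc, warnings),
#' `biomarkers.csv` (one row per measurement), `landmarks.csv`, and
#' `summary.png`. Output is deterministic: rerunning with identical inputs
#' and configuration produces byte-identical JSON.
#'
#' @param report an `aorta_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_json_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE,
                       na = "null", null = "null")
  rows <- list()
  if (!is.null(report$measurements) && nrow(report$measurements)) {
    m <- report$measurements
    rows[[1]] <- data.frame(name = paste0(m$name, "_max_diameter"),
                            segment = m$segment,
                            arc_length_mm = m$arc_length_mm,
                            value = m$max_diameter_mm, units = "mm",
                            flags = ifelse(m$qc_pass, "", "qc_fail"))
    rows[[2]] <- data.frame(name = paste0(m$name, "_csa"),
                            segment = m$segment,
                            arc_length_mm = m$arc_length_mm,
                            value = m$csa_mm2, units = "mm2",
                            flags = ifelse(m$qc_pass, "", "qc_fail"))
  }
  for (ti in report$tortuosity)
    rows[[length(rows) + 1]] <-
      data.frame(name = paste0(ti$name, "_tortuosity"), segment = ti$name,
                 arc_length_mm = NA_real_, value = ti$index, units = "",
                 flags = "")
  if (!is.null(report$lumen))
    rows[[length(rows) + 1]] <-
      data.frame(name = "calcification_ratio", segment = "aorta",
                 arc_length_mm = NA_real_,
                 value = report$lumen$calcification_ratio_percent,
                 units = "percent", flags = "")
  if (length(rows))
    utils::write.csv(do.call(rbind, rows),
                     file.path(dir, "biomarkers.csv"), row.names = FALSE)
  utils::write.csv(report$landmarks, file.path(dir, "landmarks.csv"),
                   row.names = FALSE)
  grDevices::png(file.path(dir, "summary.png"), width = 1200, height = 700)
  on.exit(grDevices::dev.off())
  plot(report)
  invisible(dir)
}

#' Summary figure: CSA profile with measurement markers
#'
#' @param x an `aorta_report`.
#' @param ... ignored.
#' @export
plot.aorta_report <- function(x, ...) {
  if (is.null(x$csa) || !nrow(x$csa)) {
    graphics::plot.new()
    graphics::title(main = sprintf("scan %s: %s", x$status,
                                   x$classification$class))
    return(invisible(x))
  }
  graphics::plot(x$csa$arc_length_mm, x$csa$area_mm2, type = "l", lwd = 2,
                 col = "steelblue",
                 xlab = "arc length from the iliac bifurcation (mm)",
                 ylab = expression(paste("cross-sectional area (", mm^2, ")")),
                 main = sprintf("aortic CSA profile (status: %s, class: %s)",
                                x$status, x$classification$class))
  if (!is.null(x$segments) && nrow(x$segments)) {
    bnd <- sort(unique(c(x$segments$start_mm, x$segments$end_mm)))
    graphics::abline(v = bnd, col = "grey70", lty = 3)
    mid <- (x$segments$start_mm + x$segments$end_mm) / 2
    graphics::mtext(x$segments$segment, side = 3, at = mid, cex = 0.8,
                    col = "grey40")
  }
  if (!is.null(x$measurements) && nrow(x$measurements)) {
    m <- x$measurements
    graphics::points(m$arc_length_mm, m$csa_mm2,
                     pch = ifelse(m$qc_pass, 19, 4),
                     col = ifelse(m$qc_pass, "firebrick", "orange"), cex = 1.4)
    graphics::text(m$arc_length_mm, m$csa_mm2,
                   sprintf("%s: %.1f mm", m$name, m$max_diameter_mm),
                   pos = 3, cex = 0.8)
  }
  invisible(x)
}
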