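# Voxel morphology built on the Euclidean feature/distance transform.
# Structuring elements are metric balls specified in mm, so anisotropic
# spacings are handled without per-axis voxel arithmetic.

#' Euclidean distance transform
#'
#' Distance (mm) from every voxel to the nearest `TRUE` voxel of `mask`,
#' together with the linear index of that nearest voxel (the feature
#' transform).
#'
#' @param mask logical 3-D array of seed voxels.
#' @param spacing per-axis voxel size in mm.
#' @return list with `dist` (numeric array, mm) and `feature` (integer array
#'   of 1-based linear seed indices; 0 where no seed exists).
#' @export
distance_transform <- function(mask, spacing) {
  d <- dim(mask)
  res <- cpp_ft_edt(as.logical(mask), as.integer(d), as.numeric(spacing))
  list(dist = array(res$dist, d), feature = array(res$feature, d))
}

# distance from each voxel to the mask boundary, measured inside the mask
# (distance to nearest background voxel; ~half a voxel at the surface)
distance_to_boundary <- function(mask, spacing) {
  dt <- distance_transform(!mask, spacing)
  out <- dt$dist
  out[!mask] <- 0
  out
}

#' Morphological operations with metric ball structuring elements
#'
#' @param mask logical 3-D array.
#' @param radius_mm ball radius in mm; values below the smallest voxel size
#'   still act on the 6-neighborhood because distances are voxel-center based.
#' @param spacing per-axis voxel size in mm.
#' @return logical array of the same shape.
#' @export
dilate_mask <- function(mask, radius_mm, spacing) {
  if (radius_mm <= 0 || !any(mask)) return(mask)
  dt <- distance_transform(mask, spacing)
  dt$dist <= radius_mm
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, radius_mm, spacing) {
  if (radius_mm <= 0 || !any(mask)) return(mask)
  dt <- distance_transform(!mask, spacing)
  mask & dt$dist > radius_mm
}

#' @rdname dilate_mask
#' @export
open_mask <- function(mask, radius_mm, spacing) {
  dilate_mask(erode_mask(mask, radius_mm, spacing), radius_mm, spacing)
}

#' @rdname dilate_mask
#' @export
close_mask <- function(mask, radius_mm, spacing) {
  erode_mask(dilate_mask(mask, radius_mm, spacing), radius_mm, spacing)
}

#' Connected components (26-connectivity)
#'
#' @param mask logical 3-D array.
#' @return integer array of component labels (0 = background) with attribute
#'   `n_components`.
#' @export
connected_components <- function(mask) {
  d <- dim(mask)
  lab <- cpp_label_components(as.logical(mask), as.integer(d))
  n <- attr(lab, "n_components")
  lab <- array(lab, d)
  attr(lab, "n_components") <- n
  lab
}

# keep components at least min_mm3 in volume; returns logical mask
drop_small_components <- function(mask, spacing, min_mm3) {
  lab <- connected_components(mask)
  n <- attr(lab, "n_components")
  if (n == 0) return(mask & FALSE)
  vol_vox <- prod(spacing)
  sizes <- tabulate(lab[lab > 0L], nbins = n) * vol_vox
  keep <- which(sizes >= min_mm3)
  array(lab %in% keep, dim(mask))
}

#' Morphological 3-D skeletonization
#'
#' Thins a mask to a curve skeleton by iteratively deleting simple border
#' voxels (topology-preserving, curve endpoints kept). Optional anchor
#' voxels are never deleted; anchoring the ridge of the distance transform
#' keeps the skeleton medial and prevents highly symmetric tubes from
#' collapsing axially.
#'
#' @param mask logical 3-D array.
#' @param anchor optional logical array of protected voxels.
#' @return logical array of skeleton voxels (always a subset of `mask`).
#' @export
skeletonize <- function(mask, anchor = NULL) {
  d <- dim(mask)
  array(cpp_thin(as.logical(mask), as.integer(d),
                 if (!is.null(anchor)) as.logical(anchor)), d)
}

#' Fill interior holes of a mask
#'
#' Background components not connected to the grid boundary are set to TRUE.
#'
#' @param mask logical 3-D array.
#' @return logical array with enclosed cavities filled.
#' @export
fill_holes <- function(mask) {
  bg <- connected_components(!mask)
  n <- attr(bg, "n_components")
  if (n <= 1) return(mask | (bg > 0 & FALSE))
  d <- dim(mask)
  edge <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ], bg[, , c(1, d[3])]))
  interior <- setdiff(seq_len(n), edge)
  if (length(interior)) mask[bg %in% interior] <- TRUE
  mask
}

# separable Gaussian smoothing of a numeric array (sigma in voxels per axis)
gaussian_smooth <- function(arr, sigma_vox) {
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    s <- sigma_vox[min(ax, length(sigma_vox))]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-((-half:half)^2) / (2 * s^2))
    k <- k / sum(k)
    acc <- array(0, d)
    for (j in seq_along(k)) {
      sh <- j - half - 1L
      idx_src <- pmin(pmax(seq_len(d[ax]) + sh, 1L), d[ax]) # replicate edges
      acc <- acc + k[j] * slice_index(out, ax, idx_src)
    }
    out <- acc
  }
  out
}

# 26-neighborhood maximum filter (edges replicated)
max_filter3 <- function(arr) {
  d <- dim(arr)
  out <- arr
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    ix <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    iy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    iz <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    out <- pmax(out, arr[ix, iy, iz])
  }
  out
}

# index array along one axis with a vector of source indices
slice_index <- function(arr, axis, idx) {
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}
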