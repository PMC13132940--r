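#' Image and label volumes
#'
#' An `aorta_image` holds a 3-D grid of Hounsfield units together with its
#' physical geometry: per-axis voxel spacing (mm) and the world position of
#' the first voxel (mm). The internal anatomical convention is RAS: the three
#' array axes run left-to-right, posterior-to-anterior and
#' inferior-to-superior, so "superior" always means increasing third index.
#' All downstream geometry is computed in world millimetres; voxel indices
#' only appear inside rasterization and resampling kernels.
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing numeric length-3, voxel size in mm (strictly positive).
#' @param origin numeric length-3, world position (mm) of voxel (1,1,1).
#' @return An object of class `aorta_image`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stop("non-3D input: voxels must be a 3-D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), space = "RAS"),
            class = "aorta_image")
}

#' @export
print.aorta_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<aorta_image> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm (RAS)\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.1f, %.1f, %.1f) mm, HU range [%.0f, %.0f]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Default anatomical label vocabulary
#'
#' Structure names mirror the TotalSegmentator conventions used by the
#' upstream segmentation so that real label maps drop in unchanged; integer
#' ids are the values stored in the label volume.
#' @return Named integer vector mapping structure name to label id.
#' @export
default_vocabulary <- function() {
  c(aorta = 1L, lv_blood = 2L, rv_blood = 3L, liver = 4L,
    kidney_left = 5L, kidney_right = 6L, brachiocephalic_trunk = 7L,
    left_common_carotid = 8L, left_subclavian = 9L,
    iliac_left = 10L, iliac_right = 11L)
}

#' Construct a label volume
#'
#' @param voxels 3-D integer array aligned with an [image_volume()].
#' @param spacing,origin geometry, as for [image_volume()].
#' @param vocabulary named integer vector mapping structure names to ids.
#' @return An object of class `aorta_labels`; structures from the vocabulary
#'   absent from the grid are recorded in `$missing`.
#' @export
label_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         vocabulary = default_vocabulary()) {
  if (length(dim(voxels)) != 3L) stop("non-3D input: label grid must be 3-D")
  present <- sort(unique(as.integer(voxels)))
  missing <- names(vocabulary)[!vocabulary %in% present]
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), vocabulary = vocabulary,
                 missing = missing, space = "RAS"),
            class = "aorta_labels")
}

#' @export
print.aorta_labels <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<aorta_labels> %d x %d x %d voxels, %d/%d structures present\n",
              d[1], d[2], d[3],
              length(x$vocabulary) - length(x$missing), length(x$vocabulary)))
  if (length(x$missing))
    cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Extract the binary mask of one structure
#' @param labels an `aorta_labels` object.
#' @param name structure name present in the vocabulary.
#' @return logical 3-D array (all-FALSE if the structure is missing).
#' @export
structure_mask <- function(labels, name) {
  id <- labels$vocabulary[[name]]
  if (is.null(id)) stop("unknown structure: ", name)
  labels$voxels == id
}

# world coordinates (mm) of 1-based voxel indices (n x 3 matrix)
voxel_to_world <- function(vol, idx) {
  idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

# nearest 1-based voxel indices of world points (n x 3)
world_to_voxel <- function(vol, pts) {
  pts <- matrix(pts, ncol = 3)
  idx <- round(sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")) + 1
  d <- dim(vol$voxels)
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 1), d[a])
  idx
}

# linear (column-major) index from n x 3 voxel indices
voxel_to_linear <- function(dims, idx) {
  idx <- matrix(idx, ncol = 3)
  (idx[, 3] - 1) * dims[1] * dims[2] + (idx[, 2] - 1) * dims[1] + idx[, 1]
}

# world coordinates (mm) of linear indices
linear_to_world <- function(vol, lin) {
  voxel_to_world(vol, arrayInd(lin, dim(vol$voxels)))
}

has_extension <- function(path, exts) {
  low <- tolower(path)
  any(vapply(exts, function(e) endsWith(low, e), logical(1)))
}

#' Read a CT volume
#'
#' Reads a NIfTI (`.nii`, `.nii.gz`) or NRRD (`.nrrd`) scalar volume,
#' reorients the data to the internal RAS convention and returns an
#' [image_volume()]. HU values are returned as stored (after any NIfTI
#' scaling slope/intercept applied by the reader).
#'
#' @param path path to the image file.
#' @return An `aorta_image`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (has_extension(path, c(".nii", ".nii.gz"))) {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L) stop("non-3D input: ", path)
    if (!identical(RNifti::orientation(img), "RAS"))
      RNifti::orientation(img) <- "RAS"
    xf <- RNifti::xform(img)
    image_volume(as.array(img), spacing = RNifti::pixdim(img)[1:3],
                 origin = xf[1:3, 4])
  } else if (has_extension(path, ".nrrd")) {
    v <- read_nrrd(path)
    image_volume(v$data, spacing = v$spacing, origin = v$origin)
  } else {
    stop("unrecognized format (expected .nii, .nii.gz or .nrrd): ", path)
  }
}

#' Read an anatomical label map
#'
#' @param path path to a NIfTI or NRRD integer label map.
#' @param vocabulary named integer vector of expected structures.
#' @param reference optional `aorta_image` whose geometry the labels must
#'   match (shape exactly; spacing and origin within `tol` mm).
#' @param tol geometry tolerance in mm.
#' @param strict error on label ids absent from the vocabulary.
#' @return An `aorta_labels`; structures not found in the map are listed in
#'   `$missing` rather than silently zero-filled.
#' @export
read_labels <- function(path, vocabulary = default_vocabulary(),
                        reference = NULL, tol = 1e-3, strict = FALSE) {
  img <- read_image(path)
  vox <- img$voxels
  storage.mode(vox) <- "integer"
  if (!is.null(reference)) {
    if (!identical(dim(vox), dim(reference$voxels)))
      stop("geometry mismatch: label grid shape differs from reference image")
    if (max(abs(img$spacing - reference$spacing)) > tol ||
        max(abs(img$origin - reference$origin)) > tol)
      stop("geometry mismatch: label spacing/origin differs from reference image")
  }
  if (strict) {
    ids <- setdiff(unique(as.integer(vox)), c(0L, unname(vocabulary)))
    if (length(ids)) stop("unknown label ids: ", paste(ids, collapse = ", "))
  }
  label_volume(vox, spacing = img$spacing, origin = img$origin,
               vocabulary = vocabulary)
}

#' Write a volume to NIfTI or NRRD
#'
#' @param vol an `aorta_image` or `aorta_labels`.
#' @param path output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vox <- vol$voxels
  if (has_extension(path, c(".nii", ".nii.gz"))) {
    img <- RNifti::asNifti(vox)
    m <- diag(c(vol$spacing, 1))
    m[1:3, 4] <- vol$origin
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  } else if (has_extension(path, ".nrrd")) {
    write_nrrd(vox, path, spacing = vol$spacing, origin = vol$origin)
  } else {
    stop("unrecognized output format: ", path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal NRRD support: 3-D volumes, raw/gzip encodings, little endian,
# diagonal space directions. (No installed package reads NRRD.)

nrrd_types <- c("signed char" = "int8", "int8" = "int8", "int8_t" = "int8",
                "uchar" = "uint8", "unsigned char" = "uint8", "uint8" = "uint8",
                "short" = "int16", "signed short" = "int16", "int16" = "int16",
                "ushort" = "uint16", "unsigned short" = "uint16", "uint16" = "uint16",
                "int" = "int32", "signed int" = "int32", "int32" = "int32",
                "float" = "float32", "double" = "float64")

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || nchar(line) == 0) break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) == 2)
      hdr[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  ndim <- as.integer(hdr$dimension)
  if (is.na(ndim) || ndim != 3L) stop("non-3D input: NRRD dimension != 3")
  sizes <- as.integer(strsplit(hdr$sizes, "\\s+")[[1]])
  type <- nrrd_types[[tolower(hdr$type)]]
  if (is.null(type)) stop("unsupported NRRD type: ", hdr$type)
  enc <- tolower(hdr$encoding)
  spacing <- c(1, 1, 1)
  origin <- c(0, 0, 0)
  if (!is.null(hdr[["space directions"]])) {
    vecs <- regmatches(hdr[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", hdr[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    if (any(abs(m[!diag(3) > 0]) > 1e-9))
      stop("unsupported NRRD: non-diagonal space directions")
    spacing <- abs(diag(m))
  } else if (!is.null(hdr$spacings)) {
    spacing <- as.numeric(strsplit(hdr$spacings, "\\s+")[[1]])
  }
  if (!is.null(hdr[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", hdr[["space origin"]]), ",")[[1]])
  n <- prod(sizes)
  bytes <- c(int8 = 1L, uint8 = 1L, int16 = 2L, uint16 = 2L,
             int32 = 4L, float32 = 4L, float64 = 8L)[[type]]
  raw <- readBin(con, "raw", n = file.size(path))
  if (enc %in% c("gzip", "gz")) raw <- memDecompress(raw, type = "gzip")
  else if (enc != "raw") stop("unsupported NRRD encoding: ", enc)
  what <- if (type %in% c("float32", "float64")) "double" else "integer"
  size <- bytes
  signed <- !startsWith(type, "uint")
  data <- readBin(raw, what, n = n, size = size, signed = signed,
                  endian = "little")
  list(data = array(data, dim = sizes), spacing = spacing, origin = origin)
}

write_nrrd <- function(vox, path, spacing, origin) {
  is_int <- is.integer(vox) || all(vox == round(vox))
  type <- if (is_int) "int" else "double"
  hdr <- c("NRRD0004",
           sprintf("type: %s", type),
           "dimension: 3",
           "space: right-anterior-superior",
           sprintf("sizes: %d %d %d", dim(vox)[1], dim(vox)[2], dim(vox)[3]),
           sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
                   spacing[1], spacing[2], spacing[3]),
           "endian: little",
           "encoding: gzip",
           sprintf("space origin: (%g,%g,%g)", origin[1], origin[2], origin[3]),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  payload <- if (is_int) {
    v <- vox; storage.mode(v) <- "integer"
    writeBin(as.vector(v), raw(), size = 4, endian = "little")
  } else {
    writeBin(as.vector(as.numeric(vox)), raw(), size = 8, endian = "little")
  }
  writeBin(memCompress(payload, type = "gzip"), con)
  invisible(path)
}
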