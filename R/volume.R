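# Voxel volumes, ROI masks and grey-level discretization.
#
# Arrays are indexed (x, y, z), 0-based geometry carried as `origin`; spacing
# is in mm and strictly positive. Texture offsets downstream are in voxel
# units; spacing is consumed only by the shape features.

#' Construct a voxel volume
#'
#' A 3D scalar grid (intensities in arbitrary units emulating HU) with
#' anisotropic voxel spacing in mm.
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, voxel size in mm (dx, dy, dz), all > 0.
#' @param origin Numeric length-3, position of the first voxel centre in mm.
#' @return An object of class `voxel_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) geometry_error("volume data must be a 3D array")
  if (any(dim(data) < 1L)) geometry_error("all three dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    parameter_error("spacing must be three strictly positive numbers (mm)")
  if (any(!is.finite(data))) data_error("volume contains non-finite voxels")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "voxel_volume")
}

#' Construct an ROI mask
#'
#' Binary region of interest congruent with a voxel volume. Any input is
#' binarized at > 0 so probabilistic or integer label masks are tolerated.
#'
#' @param mask 3D array; voxels with value > 0 are inside the region.
#' @return An object of class `roi_mask` with logical field `mask`.
#' @export
roi_mask <- function(mask) {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L) geometry_error("mask must be a 3D array")
  m <- !is.na(mask) & mask > 0
  dim(m) <- dim(mask)
  if (!any(m)) empty_roi_error("mask selects no voxels")
  structure(list(mask = m), class = "roi_mask")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s grid, %d voxels in ROI\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' Write a volume or mask to NIfTI
#'
#' @param volume A `voxel_volume`, `roi_mask`, or plain 3D array.
#' @param path Output path (.nii or .nii.gz).
#' @param spacing Spacing in mm; taken from the object when it carries one.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, spacing = NULL) {
  if (inherits(volume, "voxel_volume")) {
    arr <- volume$data
    if (is.null(spacing)) spacing <- volume$spacing
  } else if (inherits(volume, "roi_mask")) {
    arr <- volume$mask + 0
  } else {
    arr <- as.array(volume)
  }
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_volume <- function(path) {
  if (!file.exists(path)) data_error(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))  # drop RNifti attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- arr[, , , 1L, drop = TRUE]
    dim(arr) <- dim(arr)[1:3]
  }
  if (length(dim(arr)) != 3L)
    geometry_error(sprintf("%s does not decode as a 3D image", path))
  hdr <- RNifti::niftiHeader(img)
  spacing <- abs(as.numeric(hdr$pixdim[2:4]))
  spacing[spacing == 0] <- 1
  origin <- as.numeric(c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z))
  list(data = arr, spacing = spacing, origin = origin)
}

#' Load a volume and its congruent ROI mask
#'
#' Reads a scalar volume and a mask volume (NIfTI), validates geometry, and
#' binarizes the mask at > 0.
#'
#' @param volume_path Path to the intensity volume (.nii/.nii.gz).
#' @param mask_path Path to the mask volume (same grid).
#' @param tol Relative tolerance for spacing agreement (default 1e-3).
#' @return A list with elements `volume` (`voxel_volume`) and `mask`
#'   (`roi_mask`).
#' @export
load_volume_and_mask <- function(volume_path, mask_path, tol = 1e-3) {
  v <- read_nifti_volume(volume_path)
  m <- read_nifti_volume(mask_path)
  if (!identical(dim(v$data), dim(m$data)))
    geometry_error(sprintf(
      "volume grid %s does not match mask grid %s",
      paste(dim(v$data), collapse = "x"), paste(dim(m$data), collapse = "x")))
  rel <- abs(v$spacing - m$spacing) / pmax(abs(v$spacing), .Machine$double.eps)
  if (any(rel > tol))
    geometry_error("volume and mask spacings disagree beyond tolerance")
  if (any(!is.finite(v$data))) data_error("volume contains non-finite voxels")
  vol <- voxel_volume(v$data, v$spacing, v$origin)
  msk <- roi_mask(m$data)
  list(volume = vol, mask = msk)
}

#' Discretize ROI intensities into integer grey levels
#'
#' Maps in-mask intensities onto levels 1..`n_bins` with equal-width bins.
#' In `relative` mode the bins span the in-mask min..max (the maximum falls
#' in bin `n_bins`); in `absolute` mode they span caller-supplied `bounds`,
#' with out-of-range intensities clamped to the end bins. A constant-intensity
#' ROI is legal: every voxel gets level 1 and `degenerate` is flagged.
#'
#' @param volume A `voxel_volume`.
#' @param mask A `roi_mask` on the same grid.
#' @param n_bins Number of grey levels Ng (>= 2); default 64.
#' @param mode `"relative"` (default) or `"absolute"`.
#' @param bounds Length-2 numeric (lo, hi) for absolute mode.
#' @return An object of class `discretized_roi`: `levels` (3D integer array,
#'   0 outside the mask), `n_levels`, `bin_edges` (length Ng + 1),
#'   `degenerate` flag and the number of in-mask voxels `n_voxels`.
#' @export
discretize <- function(volume, mask, n_bins = 64L,
                       mode = c("relative", "absolute"), bounds = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "voxel_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$data), dim(mask$mask)))
    geometry_error("volume and mask grids differ")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) parameter_error("n_bins must be >= 2")

  inmask <- mask$mask
  x <- volume$data[inmask]
  degenerate <- FALSE

  if (mode == "relative") {
    lo <- min(x); hi <- max(x)
    if (hi <= lo) {
      degenerate <- TRUE
      lev <- rep.int(1L, length(x))
      edges <- seq(lo - 0.5, lo + 0.5, length.out = n_bins + 1L)
    } else {
      edges <- seq(lo, hi, length.out = n_bins + 1L)
      lev <- pmin(as.integer(floor((x - lo) / (hi - lo) * n_bins)) + 1L, n_bins)
    }
  } else {
    if (is.null(bounds) || length(bounds) != 2L)
      parameter_error("absolute mode requires bounds = c(lo, hi)")
    lo <- bounds[1]; hi <- bounds[2]
    if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
      parameter_error("absolute bounds need lo < hi")
    edges <- seq(lo, hi, length.out = n_bins + 1L)
    lev <- as.integer(floor((x - lo) / (hi - lo) * n_bins)) + 1L
    lev <- pmin(pmax(lev, 1L), n_bins)
  }

  levels <- array(0L, dim = dim(inmask))
  levels[inmask] <- lev
  structure(list(levels = levels, n_levels = n_bins, bin_edges = edges,
                 degenerate = degenerate, n_voxels = length(x)),
            class = "discretized_roi")
}

#' @export
print.discretized_roi <- function(x, ...) {
  cat(sprintf("<discretized_roi> Ng=%d, %d voxels in ROI%s\n",
              x$n_levels, x$n_voxels,
              if (x$degenerate) " (degenerate: constant intensity)" else ""))
  invisible(x)
}
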