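#' Construct a 3D image volume
#'
#' Light-weight container for a 3D scalar grid with anisotropic voxel
#' spacing, the carrier of raw and normalized T1-weighted intensities.
#'
#' @param voxels 3D numeric array of voxel intensities.
#' @param spacing_mm numeric length-3, per-axis voxel size in mm.
#' @param origin numeric length-3 physical offset of the first voxel centre.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing_mm = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (any(!is.finite(voxels)))
    stop("voxel intensities must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive values")
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing_mm), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Fat-referenced intensity normalization (NIV)
#'
#' Rescales raw T1-weighted intensities to normalized intensity values:
#' each voxel is divided by the mean intensity within a fat-reference ROI
#' and multiplied by 1000, so a voxel at the reference mean maps to
#' NIV = 1000.  This adjusts for scanner/protocol differences before
#' radiomic feature extraction.
#'
#' @param volume an [image_volume] (or bare 3D array).
#' @param reference_mask logical array of the same geometry marking the
#'   fat-reference ROI.
#' @return An object of class `normalized_volume` with elements `voxels`
#'   (NIV values), `reference_mean` (the denominator, raw units) and
#'   `spacing_mm`.
#' @export
normalize_niv <- function(volume, reference_mask) {
  vox <- if (inherits(volume, "image_volume")) volume$voxels else volume
  spacing <- if (inherits(volume, "image_volume")) volume$spacing_mm else
    c(1, 1, 1)
  if (!identical(dim(vox), dim(reference_mask)))
    stop("reference mask geometry does not match the volume")
  reference_mask <- as.logical(reference_mask)
  if (!any(reference_mask)) stop("reference mask is empty")
  m <- mean(vox[reference_mask])
  if (!is.finite(m) || m <= 0)
    stop("reference-ROI mean must be strictly positive, got ", format(m))
  structure(list(voxels = vox / m * 1000, reference_mean = m,
                 spacing_mm = spacing),
            class = "normalized_volume")
}

#' @export
print.normalized_volume <- function(x, ...) {
  cat("<normalized_volume> reference mean ", format(x$reference_mean),
      " (raw units); NIV grid ", paste(dim(x$voxels), collapse = " x "),
      "\n", sep = "")
  invisible(x)
}

#' Discretize ROI intensities into gray levels
#'
#' Fixed-bin-width, minimum-shifted discretization used by all texture
#' matrix families: `level(x) = floor((x - min_ROI) / bin_width) + 1`.
#' The returned level array is cropped to the ROI bounding box with `NA`
#' outside the ROI, which texture kernels treat as "not in ROI".
#'
#' @param normalized a `normalized_volume` (or bare 3D numeric array).
#' @param roi_mask logical array of the same geometry.
#' @param bin_width bin width in NIV units (default 25).
#' @return An object of class `gray_level_map` with `levels` (integer array,
#'   ROI bounding box), `n_levels`, `bin_width`, `n_voxels`.
#' @export
discretize <- function(normalized, roi_mask, bin_width = 25) {
  vox <- if (inherits(normalized, "normalized_volume")) normalized$voxels
         else normalized
  if (!identical(dim(vox), dim(roi_mask)))
    stop("ROI mask geometry does not match the volume")
  roi_mask <- array(as.logical(roi_mask), dim = dim(vox))
  if (!any(roi_mask)) stop("ROI is empty")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a single positive number")
  bb <- mask_bbox(roi_mask)
  vox <- vox[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2],
             drop = FALSE]
  roi <- roi_mask[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2],
                  drop = FALSE]
  lv <- array(NA_integer_, dim = dim(vox))
  x <- vox[roi]
  lv[roi] <- as.integer(floor((x - min(x)) / bin_width)) + 1L
  structure(list(levels = lv, n_levels = max(lv, na.rm = TRUE),
                 bin_width = bin_width, n_voxels = sum(roi)),
            class = "gray_level_map")
}

# bounding box of a logical 3D array: 3 x 2 matrix of index ranges
mask_bbox <- function(mask) {
  b <- cpp_bbox(mask, dim(mask))
  if (length(b) == 0L) stop("mask is empty")
  matrix(b, 3, 2, byrow = TRUE)
}
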