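#' 3D image volumes and segmentation masks
#'
#' `image_volume()` wraps a 3D numeric array of scalar intensities (e.g. HU)
#' together with its per-axis voxel spacing in millimetres. `seg_mask()` wraps
#' a logical 3D array aligned to such a volume. Both are plain arrays with a
#' `spacing` attribute and a class, so all base array operations keep working.
#'
#' @param data 3D numeric (volume) or logical/0-1 (mask) array.
#' @param spacing numeric length-3, voxel spacing in mm per axis.
#' @return An `image_volume` or `seg_mask` object.
#' @examples
#' v <- image_volume(array(rnorm(8 * 8 * 8), c(8, 8, 8)), spacing = c(1, 1, 2))
#' m <- seg_mask(array(TRUE, c(8, 8, 8)), spacing = c(1, 1, 2))
#' voxel_volume(v)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L)
    stopf("an image volume must be a 3D array, got %d dimension(s)",
          length(dim(data)))
  if (!is.numeric(data)) stopf("volume data must be numeric")
  if (any(!is.finite(data))) stopf("volume intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 positive finite numbers (mm)")
  structure(data, spacing = spacing, class = c("image_volume", "array"))
}

#' @rdname image_volume
#' @export
seg_mask <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L)
    stopf("a segmentation mask must be a 3D array, got %d dimension(s)",
          length(dim(data)))
  d <- dim(data)
  data <- as.logical(data)
  if (anyNA(data)) stopf("mask voxels must be TRUE/FALSE or 0/1")
  dim(data) <- d
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be 3 positive finite numbers (mm)")
  structure(data, spacing = spacing, class = c("seg_mask", "array"))
}

#' @rdname image_volume
#' @param x an `image_volume` or `seg_mask`.
#' @export
spacing <- function(x) attr(x, "spacing") %||% c(1, 1, 1)

#' @rdname image_volume
#' @export
voxel_volume <- function(x) prod(spacing(x))

# Drop class/attrs down to a bare array (internal).
as_array <- function(x) {
  a <- unclass(x)
  attr(a, "spacing") <- NULL
  a
}

# Validate that a mask is aligned to a volume (same grid, same spacing).
check_aligned <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask)))
    stopf("volume grid %s and mask grid %s do not match",
          paste(dim(volume), collapse = "x"),
          paste(dim(mask), collapse = "x"))
  sv <- spacing(volume); sm <- spacing(mask)
  if (max(abs(sv - sm)) > 1e-9)
    stopf("volume spacing (%s) and mask spacing (%s) do not match",
          paste(signif(sv, 6), collapse = ", "),
          paste(signif(sm, 6), collapse = ", "))
  invisible(TRUE)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, range [%.4g, %.4g]\n",
              paste(dim(x), collapse = "x"),
              paste(signif(spacing(x), 4), collapse = "x"),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %s voxels, spacing %s mm, %d foreground (%.3g mm^3)\n",
              paste(dim(x), collapse = "x"),
              paste(signif(spacing(x), 4), collapse = "x"),
              sum(x), sum(x) * voxel_volume(x)))
  invisible(x)
}

#' Dice similarity coefficient between two masks
#'
#' @param a,b `seg_mask` objects (or logical arrays) on the same grid.
#' @return Dice coefficient in `[0, 1]`; 1 for two empty masks.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("masks are on different grids")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}
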