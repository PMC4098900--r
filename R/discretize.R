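#' Discretize in-mask intensities into gray levels
#'
#' Fixed bin-width discretization used for the texture matrices and the
#' histogram-based first-order features:
#' `level(v) = 1 + floor((I(v) - min_in_mask) / bin_width)`.
#'
#' @param volume `image_volume` (or 3D numeric array).
#' @param mask `seg_mask` aligned with `volume`.
#' @param bin_width bin width in intensity units (HU), default 25.
#' @return a `discretized_volume`: list with `levels` (integer array, 0
#'   outside the mask), `L` (number of levels), `bin_width`, `min_intensity`.
#' @examples
#' v <- array(c(0, 24, 25, 49, 0, 0, 0, 0), c(2, 2, 2))
#' m <- array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), c(2, 2, 2))
#' discretize(v, m, 25)$L  # 2
#' @export
discretize <- function(volume, mask, bin_width = 25) {
  if (!identical(dim(volume), dim(mask))) stopf("volume and mask grids differ")
  if (!any(mask)) stopf("cannot discretize an empty mask")
  if (!is.finite(bin_width) || bin_width <= 0) stopf("bin_width must be > 0")
  vals <- as.numeric(volume)[as.logical(mask)]
  mn <- min(vals)
  lev <- array(0L, dim(volume))
  lev[as.logical(mask)] <- 1L + as.integer(floor((vals - mn) / bin_width))
  structure(list(levels = lev, L = max(lev), bin_width = bin_width,
                 min_intensity = mn),
            class = "discretized_volume")
}

#' @export
print.discretized_volume <- function(x, ...) {
  cat(sprintf("<discretized_volume> %d level(s), bin width %g, min %g\n",
              x$L, x$bin_width, x$min_intensity))
  invisible(x)
}
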