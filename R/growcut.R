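#' GrowCut competitive region-growing segmentation
#'
#' GrowCut segments an image by cellular automaton: every voxel carries a
#' class label and a strength in \[0, 1\]. Seeded voxels start with their
#' user-given label at strength 1; at each synchronous iteration a labeled
#' neighbor `q` conquers voxel `p` when `g(|C_p - C_q|) * theta_q > theta_p`,
#' where `g(x) = 1 - x / max_intensity_difference` and the intensity scale is
#' fixed over the region of interest (ROI) before iterating. The ROI is the
#' discrete convex hull of all seeded voxels dilated by a voxel margin;
#' voxels outside it never change. The automaton converges when a full sweep
#' changes no label (strengths are bounded and monotone, so they cannot cycle).
#'
#' @param volume an `image_volume` (or 3D numeric array).
#' @param seeds integer 3D array aligned with `volume`: 0 = unlabeled,
#'   1, 2, ... = class seeds. Two-class use is foreground = 1, background = 2.
#' @param margin_voxels ROI margin added around the convex hull of the seeds
#'   (Chebyshev dilation), default 2.
#' @param max_iters iteration cap, default 500.
#' @param connectivity automaton neighborhood: 26 (default) or 6.
#' @return A `growcut_result`: list with `labels` (integer array; 0 outside
#'   the reached region), `strength`, `roi`, `iterations`, `converged`.
#' @examples
#' vol <- array(0, c(7, 7, 7)); vol[3:5, 3:5, 3:5] <- 100
#' seeds <- array(0L, c(7, 7, 7))
#' seeds[4, 4, 4] <- 1L; seeds[1, 1, 1] <- 2L; seeds[7, 7, 7] <- 2L
#' r <- growcut(vol, seeds, margin_voxels = 6)
#' sum(r$labels == 1)  # the 27 bright voxels
#' @export
growcut <- function(volume, seeds, margin_voxels = 2, max_iters = 500,
                    connectivity = 26) {
  if (!identical(dim(volume), dim(seeds)))
    stopf("volume and seed grids do not match")
  if (any(!is.finite(volume))) stopf("volume intensities must be finite")
  seeds <- as.integer(seeds)
  dim(seeds) <- dim(volume)
  if (any(seeds < 0L)) stopf("seed labels must be >= 0")
  classes <- sort(unique(seeds[seeds > 0L]))
  if (length(classes) < 1L) stopf("no labeled voxels in seeds")
  roi <- build_roi(seeds, margin_voxels)
  res <- cpp_growcut(as_array_keep(volume), dim(volume), seeds, roi,
                     as.integer(connectivity), as.integer(max_iters))
  structure(list(labels = res$labels, strength = res$strength, roi = roi,
                 iterations = res$iterations, converged = res$converged,
                 classes = classes),
            class = "growcut_result")
}

#' @export
print.growcut_result <- function(x, ...) {
  cat(sprintf("<growcut_result> %s after %d iteration(s); %d ROI voxel(s), classes: %s\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, sum(x$roi),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Region of interest for GrowCut
#'
#' The discrete convex hull of all labeled voxels, dilated by
#' `margin_voxels` steps of Chebyshev (26-neighborhood) dilation and clipped
#' to the grid. Exact integer half-space tests are used for the hull, so
#' collinear and coplanar seed sets are handled exactly.
#'
#' @param seeds integer label array (0 = unlabeled).
#' @param margin_voxels non-negative integer margin.
#' @return logical array marking the ROI.
#' @export
build_roi <- function(seeds, margin_voxels = 2) {
  idx <- which(seeds > 0L)
  if (length(idx) == 0L) stopf("no labeled voxels in seeds")
  d <- dim(seeds)
  coords <- arrayInd(idx, d) - 1L  # 0-based for the C++ side
  hull <- cpp_hull_mask(coords, as.integer(d))
  if (margin_voxels > 0)
    hull <- cpp_dilate_chebyshev(hull, as.integer(d), as.integer(margin_voxels))
  dim(hull) <- d
  hull
}

#' Post-process GrowCut labels into a single-component mask
#'
#' Keeps the largest 26-connected component of the chosen foreground class
#' and discards all other foreground islands (the automated stand-in for the
#' visual clean-up step of interactive use).
#'
#' @param labels integer label array or a `growcut_result`.
#' @param foreground_class which class is the tumor (default 1).
#' @param spacing optional spacing for the returned `seg_mask`.
#' @return `seg_mask` with a single connected component.
#' @export
growcut_postprocess <- function(labels, foreground_class = 1L, spacing = c(1, 1, 1)) {
  if (inherits(labels, "growcut_result")) labels <- labels$labels
  fg <- labels == foreground_class
  if (!any(fg)) stopf("no voxels of foreground class %d", foreground_class)
  dim(fg) <- dim(labels)
  seg_mask(largest_component(fg, connectivity = 26), spacing)
}
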