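# Full 56-feature panel and study-level feature matrices.

#' Names of the 56 radiomic features
#'
#' @param family optional subset: `"intensity"`, `"shape"` or `"texture"`.
#' @return character vector of stable feature names (15 intensity, 8 shape,
#'   33 texture; 56 in total).
#' @export
feature_names <- function(family = c("all", "intensity", "shape", "texture")) {
  family <- match.arg(family)
  switch(family,
         all = c(intensity_feature_names(), shape_feature_names(),
                 texture_feature_names()),
         intensity = intensity_feature_names(),
         shape = shape_feature_names(),
         texture = texture_feature_names())
}

#' Family of each feature
#' @return named character vector mapping feature name to
#'   `"intensity"`/`"shape"`/`"texture"`.
#' @export
feature_families <- function() {
  stats::setNames(rep(c("intensity", "shape", "texture"), c(15, 8, 33)),
                  feature_names())
}

#' Extract the 56-feature radiomic panel
#'
#' Concatenates the first-order intensity features, the shape features and
#' the direction-averaged texture features for one volume/mask pair.
#' Degenerate inputs yield flagged `NA` entries, never silent omissions.
#'
#' @param volume `image_volume`.
#' @param mask aligned `seg_mask`.
#' @param spacing voxel spacing; defaults to the volume's.
#' @param bin_width discretization bin width in HU (default 25).
#' @param distance co-occurrence distance in voxels (default 1).
#' @param area_mode surface-area estimator, see [shape_features()].
#' @return named numeric vector of length 56.
#' @export
extract_features <- function(volume, mask, spacing = NULL, bin_width = 25,
                             distance = 1L, area_mode = "mesh") {
  if (!is.null(attr(volume, "spacing")) && !is.null(attr(mask, "spacing")))
    check_aligned(volume, mask)
  spacing <- spacing %||% attr(volume, "spacing") %||% c(1, 1, 1)
  if (!any(mask)) stopf("mask is empty")
  disc <- discretize(volume, mask, bin_width)
  c(intensity_features(volume, mask, bin_width = bin_width),
    shape_features(mask, spacing, area_mode = area_mode),
    texture_features(disc, distance = distance))
}

#' Feature matrix for a whole study dataset
#'
#' Extracts the 56-feature panel for every (tumor, observer, run)
#' segmentation of a [generate_study()] dataset.
#'
#' @param dataset a `study_dataset`.
#' @param bin_width,distance,area_mode passed to [extract_features()].
#' @return data frame with id columns `tumor`, `group`, `observer`, `run`
#'   followed by the 56 feature columns.
#' @export
extract_study_features <- function(dataset, bin_width = 25, distance = 1L,
                                   area_mode = "mesh") {
  stopifnot(inherits(dataset, "study_dataset"))
  rows <- list()
  for (tum in dataset$tumors) {
    for (key in names(tum$masks)) {
      mm <- tum$meta[[key]]
      fv <- extract_features(tum$volume, tum$masks[[key]],
                             bin_width = bin_width, distance = distance,
                             area_mode = area_mode)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(tumor = tum$id, group = mm$group, observer = mm$observer,
                   run = mm$run, stringsAsFactors = FALSE),
        as.data.frame(as.list(fv)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a study feature matrix as CSV
#'
#' The CSV has one row per (tumor, observer, run) and a stable header; a
#' JSON sidecar (`<path>.json`) records the extraction parameters.
#'
#' @param features feature data frame from [extract_study_features()].
#' @param path CSV path.
#' @param params list of extraction parameters for the sidecar.
#' @export
write_feature_matrix <- function(features, path,
                                 params = list(bin_width = 25, distance = 1,
                                               connectivity = 26,
                                               area_mode = "mesh")) {
  write.csv(features, path, row.names = FALSE)
  jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
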