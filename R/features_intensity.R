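# First-order (intensity histogram) features of the in-mask voxel values.
#
# Moment-based features use population (biased) definitions by default, the
# convention of the radiomics feature sets this panel descends from;
# `unbiased = TRUE` switches variance/SD (and the standardization inside
# skewness/kurtosis) to n-1 denominators. Entropy and uniformity are
# computed on the same fixed-bin-width discretization as the texture
# matrices; entropy is in bits (log2). Kurtosis is non-excess (3 for a
# normal distribution).

intensity_feature_names <- function() {
  c("intensity_energy", "intensity_entropy", "intensity_iqr",
    "intensity_kurtosis", "intensity_max", "intensity_mad",
    "intensity_mean", "intensity_median", "intensity_min",
    "intensity_range", "intensity_rms", "intensity_skewness",
    "intensity_sd", "intensity_uniformity", "intensity_variance")
}

#' First-order intensity features
#'
#' The 15 histogram features of the in-mask voxel intensities: energy,
#' entropy, interquartile range, kurtosis, maximum, mean absolute deviation,
#' mean, median, minimum, range, root mean square, skewness, standard
#' deviation, uniformity and variance.
#'
#' @param volume `image_volume` (or numeric array).
#' @param mask aligned `seg_mask`.
#' @param bin_width discretization bin width for entropy/uniformity.
#' @param unbiased use n-1 denominators for variance/SD (default FALSE:
#'   population moments).
#' @return named numeric vector of length 15. For a single-voxel mask the
#'   moment features of order >= 2 are `NA` (flagged undefined).
#' @export
intensity_features <- function(volume, mask, bin_width = 25, unbiased = FALSE) {
  if (!identical(dim(volume), dim(mask))) stopf("volume and mask grids differ")
  x <- as.numeric(volume)[as.logical(mask)]
  n <- length(x)
  if (n == 0L) stopf("mask is empty")
  mu <- mean(x)
  out <- stats::setNames(numeric(15), intensity_feature_names())
  out["intensity_energy"] <- sum(x^2)
  out["intensity_max"] <- max(x)
  out["intensity_mean"] <- mu
  out["intensity_median"] <- median(x)
  out["intensity_min"] <- min(x)
  out["intensity_range"] <- max(x) - min(x)
  out["intensity_rms"] <- sqrt(mean(x^2))
  out["intensity_mad"] <- mean(abs(x - mu))
  out["intensity_iqr"] <- unname(quantile(x, 0.75) - quantile(x, 0.25))
  # histogram features share the texture discretization
  lev <- 1L + floor((x - min(x)) / bin_width)
  p <- tabulate(lev) / n
  p <- p[p > 0]
  out["intensity_entropy"] <- -sum(p * log2(p))
  out["intensity_uniformity"] <- sum(p^2)
  if (n < 2L) {
    out[c("intensity_variance", "intensity_sd", "intensity_skewness",
          "intensity_kurtosis")] <- NA_real_
    return(out)
  }
  denom <- if (unbiased) n - 1 else n
  v <- sum((x - mu)^2) / denom
  out["intensity_variance"] <- v
  out["intensity_sd"] <- sqrt(v)
  if (v > 0) {
    m2 <- sum((x - mu)^2) / n
    out["intensity_skewness"] <- (sum((x - mu)^3) / n) / m2^1.5
    out["intensity_kurtosis"] <- (sum((x - mu)^4) / n) / m2^2
  } else {
    out["intensity_skewness"] <- NA_real_
    out["intensity_kurtosis"] <- NA_real_
  }
  out
}
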