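# Texture features from gray-level co-occurrence (GLCM) and run-length
# (GLRLM) matrices, averaged over the 13 symmetric 3D directions.

#' The 13 symmetric 3D directions
#'
#' All 26-neighborhood offsets, unique up to negation (the first nonzero
#' component is positive). Their union with their negations is exactly the
#' 26-neighborhood.
#'
#' @return 13 x 3 integer matrix of direction vectors.
#' @export
direction_set <- function() {
  dirs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  dirs <- dirs[!(dirs$dx == 0 & dirs$dy == 0 & dirs$dz == 0), ]
  keep <- apply(dirs, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  m <- as.matrix(dirs[keep, ])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Symmetric counts of level pairs `(p, p + distance * direction)` with both
#' endpoints inside the mask, normalized to probabilities when
#' `normalize = TRUE`.
#'
#' @param disc a [discretize()]d volume.
#' @param direction integer length-3 offset (one of [direction_set()]).
#' @param distance voxel distance between pair members (default 1).
#' @param normalize return probabilities (default) or raw counts.
#' @return `L x L` matrix; all-zero when the direction admits no valid pair.
#' @export
glc_matrix <- function(disc, direction, distance = 1L, normalize = TRUE) {
  stopifnot(inherits(disc, "discretized_volume"))
  M <- cpp_glcm(disc$levels, dim(disc$levels), disc$L,
                as.integer(direction), as.integer(distance))
  if (normalize) {
    s <- sum(M)
    if (s > 0) M <- M / s
  }
  M
}

#' Gray-level run-length matrix for one direction
#'
#' Entry `(g, r)` counts the maximal in-mask runs of level `g` and length
#' `r` along `direction`; runs are broken by the mask boundary.
#'
#' @inheritParams glc_matrix
#' @return `L x Rmax` count matrix.
#' @export
glrl_matrix <- function(disc, direction) {
  stopifnot(inherits(disc, "discretized_volume"))
  cpp_glrlm(disc$levels, dim(disc$levels), disc$L, as.integer(direction))
}

glcm_feature_names <- function() {
  c("glcm_autocorrelation", "glcm_cluster_prominence", "glcm_cluster_shade",
    "glcm_cluster_tendency", "glcm_contrast", "glcm_correlation",
    "glcm_difference_entropy", "glcm_dissimilarity", "glcm_energy",
    "glcm_entropy", "glcm_homogeneity1", "glcm_homogeneity2",
    "glcm_imc1", "glcm_imc2", "glcm_idmn", "glcm_idn",
    "glcm_inverse_variance", "glcm_max_probability", "glcm_sum_average",
    "glcm_sum_entropy", "glcm_sum_variance", "glcm_variance")
}

glrlm_feature_names <- function() {
  c("glrlm_sre", "glrlm_lre", "glrlm_gln", "glrlm_rln", "glrlm_rp",
    "glrlm_lglre", "glrlm_hglre", "glrlm_srlgle", "glrlm_srhgle",
    "glrlm_lrlgle", "glrlm_lrhgle")
}

texture_feature_names <- function() c(glcm_feature_names(), glrlm_feature_names())

#' Haralick-type features of one co-occurrence matrix
#'
#' The 22 GLCM descriptors (entropies in bits). Correlation-type features
#' are `NA` when the marginal variance is zero (single occupied level).
#'
#' @param P normalized (probability) GLCM.
#' @return named numeric vector of length 22.
#' @export
glcm_features <- function(P) {
  L <- nrow(P)
  s <- sum(P)
  out <- stats::setNames(rep(NA_real_, 22), glcm_feature_names())
  if (s <= 0) return(out)
  P <- P / s
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:L) * px); muy <- sum((1:L) * py)
  sdx <- sqrt(sum(((1:L) - mux)^2 * px)); sdy <- sqrt(sum(((1:L) - muy)^2 * py))
  nz <- P > 0
  plog <- function(p) ifelse(p > 0, log2(p), 0)

  out["glcm_autocorrelation"] <- sum(i * j * P)
  cs <- i + j - mux - muy
  out["glcm_cluster_prominence"] <- sum(cs^4 * P)
  out["glcm_cluster_shade"] <- sum(cs^3 * P)
  out["glcm_cluster_tendency"] <- sum(cs^2 * P)
  out["glcm_contrast"] <- sum((i - j)^2 * P)
  out["glcm_correlation"] <- if (sdx > 0 && sdy > 0)
    (sum(i * j * P) - mux * muy) / (sdx * sdy) else NA_real_
  out["glcm_dissimilarity"] <- sum(abs(i - j) * P)
  out["glcm_energy"] <- sum(P^2)
  H <- -sum(P[nz] * log2(P[nz]))
  out["glcm_entropy"] <- H
  out["glcm_homogeneity1"] <- sum(P / (1 + abs(i - j)))
  out["glcm_homogeneity2"] <- sum(P / (1 + (i - j)^2))
  out["glcm_idmn"] <- sum(P / (1 + (i - j)^2 / L^2))
  out["glcm_idn"] <- sum(P / (1 + abs(i - j) / L))
  off <- i != j
  out["glcm_inverse_variance"] <- sum(P[off] / (i[off] - j[off])^2)
  out["glcm_max_probability"] <- max(P)
  # diagonal (x+y) and cross (|x-y|) marginals
  pxy_sum <- vapply(2:(2 * L), function(k) sum(P[(i + j) == k]), 0)
  pxy_dif <- vapply(0:(L - 1), function(k) sum(P[abs(i - j) == k]), 0)
  ks <- 2:(2 * L); kd <- 0:(L - 1)
  SA <- sum(ks * pxy_sum)
  out["glcm_sum_average"] <- SA
  out["glcm_sum_entropy"] <- -sum(pxy_sum * plog(pxy_sum))
  out["glcm_sum_variance"] <- sum((ks - SA)^2 * pxy_sum)
  out["glcm_difference_entropy"] <- -sum(pxy_dif * plog(pxy_dif))
  out["glcm_variance"] <- sum((i - mux)^2 * P)
  # informational measures of correlation
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  HY <- -sum(py[py > 0] * log2(py[py > 0]))
  pxpy <- outer(px, py)
  HXY1 <- -sum(P[pxpy > 0] * plog(pxpy)[pxpy > 0])
  HXY2 <- -sum(pxpy * plog(pxpy))
  out["glcm_imc1"] <- if (max(HX, HY) > 0) (H - HXY1) / max(HX, HY) else NA_real_
  arg <- 1 - exp(-2 * (HXY2 - H) * log(2))
  out["glcm_imc2"] <- sqrt(max(arg, 0))
  out
}

#' Run-length features of one GLRLM
#'
#' The 11 Galloway-type descriptors: short/long-run emphasis, gray-level and
#' run-length non-uniformity, run percentage, low/high gray-level run
#' emphasis and the four combined short/long x low/high emphases.
#'
#' @param R GLRLM count matrix (levels x run lengths).
#' @param n_voxels number of in-mask voxels traversed (for run percentage).
#' @return named numeric vector of length 11 (`NA` when the matrix is empty).
#' @export
glrlm_features <- function(R, n_voxels) {
  out <- stats::setNames(rep(NA_real_, 11), glrlm_feature_names())
  Nr <- sum(R)
  if (Nr <= 0) return(out)
  g <- row(R); r <- col(R)
  out["glrlm_sre"] <- sum(R / r^2) / Nr
  out["glrlm_lre"] <- sum(R * r^2) / Nr
  out["glrlm_gln"] <- sum(rowSums(R)^2) / Nr
  out["glrlm_rln"] <- sum(colSums(R)^2) / Nr
  out["glrlm_rp"] <- Nr / n_voxels
  out["glrlm_lglre"] <- sum(R / g^2) / Nr
  out["glrlm_hglre"] <- sum(R * g^2) / Nr
  out["glrlm_srlgle"] <- sum(R / (g^2 * r^2)) / Nr
  out["glrlm_srhgle"] <- sum(R * g^2 / r^2) / Nr
  out["glrlm_lrlgle"] <- sum(R * r^2 / g^2) / Nr
  out["glrlm_lrhgle"] <- sum(R * g^2 * r^2) / Nr
  out
}

#' Direction-averaged texture features
#'
#' Computes the 22 GLCM and 11 GLRLM features separately for each of the 13
#' symmetric directions and returns the arithmetic mean over directions
#' (directions with an undefined value are skipped for that feature).
#'
#' @param disc a [discretize()]d volume.
#' @param distance co-occurrence distance in voxels (default 1).
#' @return named numeric vector of length 33.
#' @export
texture_features <- function(disc, distance = 1L) {
  stopifnot(inherits(disc, "discretized_volume"))
  dirs <- direction_set()
  n_voxels <- sum(disc$levels > 0L)
  per_dir <- matrix(NA_real_, nrow(dirs), 33,
                    dimnames = list(NULL, texture_feature_names()))
  for (k in seq_len(nrow(dirs))) {
    P <- glc_matrix(disc, dirs[k, ], distance = distance)
    R <- glrl_matrix(disc, dirs[k, ])
    per_dir[k, ] <- c(glcm_features(P), glrlm_features(R, n_voxels))
  }
  res <- colMeans(per_dir, na.rm = TRUE)
  res[is.nan(res)] <- NA_real_  # undefined in all 13 directions
  res
}
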