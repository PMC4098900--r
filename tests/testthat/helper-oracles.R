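# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals: naive triple
# loops, explicit sum-of-squares ANOVA, exact half-space hull tests.

# --- texture matrix oracles -------------------------------------------------

naive_glcm <- function(levels, direction, L, distance = 1L) {
  d <- dim(levels)
  M <- matrix(0, L, L)
  off <- direction * distance
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
    if (x2 < 1 || y2 < 1 || z2 < 1 || x2 > d[1] || y2 > d[2] || z2 > d[3]) next
    l1 <- levels[x, y, z]; l2 <- levels[x2, y2, z2]
    if (l1 == 0 || l2 == 0) next
    M[l1, l2] <- M[l1, l2] + 1
    M[l2, l1] <- M[l2, l1] + 1
  }
  M
}

naive_glrlm <- function(levels, direction, L) {
  d <- dim(levels)
  rmax <- max(d)
  M <- matrix(0, L, rmax)
  visited <- array(FALSE, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    # start of a line: predecessor off-grid
    p <- c(x, y, z) - direction
    if (all(p >= 1) && all(p <= d)) next
    pos <- c(x, y, z)
    cur <- 0L; len <- 0L
    while (all(pos >= 1) && all(pos <= d)) {
      l <- levels[pos[1], pos[2], pos[3]]
      if (l == cur) {
        if (l != 0L) len <- len + 1L
      } else {
        if (cur != 0L) M[cur, len] <- M[cur, len] + 1
        cur <- l
        len <- if (l != 0L) 1L else 0L
      }
      pos <- pos + direction
    }
    if (cur != 0L) M[cur, len] <- M[cur, len] + 1
  }
  M[, seq_len(ncol(M)), drop = FALSE]
}

# random discretized test volume: levels 1..L inside a random mask, 0 outside
random_levels <- function(dim3 = c(6, 6, 6), L = 4, p_mask = 0.8) {
  lev <- array(0L, dim3)
  msk <- array(runif(prod(dim3)) < p_mask, dim3)
  lev[msk] <- sample.int(L, sum(msk), replace = TRUE)
  lev
}

# wrap a level array as the package's discretized_volume
as_disc <- function(levels, L = max(levels)) {
  structure(list(levels = levels, L = as.integer(L), bin_width = 1,
                 min_intensity = 0),
            class = "discretized_volume")
}

# strip class/spacing attributes down to a plain array
as_array_np <- function(x) {
  a <- unclass(x)
  attr(a, "spacing") <- NULL
  a
}

# Scalar-loop GLCM feature formulas, independent of the package's
# vectorized implementation. Entropies in bits.
naive_glcm_features <- function(P) {
  L <- nrow(P)
  s <- sum(P); P <- P / s
  px <- py <- numeric(L)
  for (i in 1:L) for (j in 1:L) { px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j] }
  mux <- sum((1:L) * px); muy <- sum((1:L) * py)
  sdx <- sqrt(sum(((1:L) - mux)^2 * px)); sdy <- sqrt(sum(((1:L) - muy)^2 * py))
  f <- c(glcm_autocorrelation = 0, glcm_cluster_prominence = 0,
         glcm_cluster_shade = 0, glcm_cluster_tendency = 0, glcm_contrast = 0,
         glcm_correlation = 0, glcm_difference_entropy = 0,
         glcm_dissimilarity = 0, glcm_energy = 0, glcm_entropy = 0,
         glcm_homogeneity1 = 0, glcm_homogeneity2 = 0, glcm_imc1 = 0,
         glcm_imc2 = 0, glcm_idmn = 0, glcm_idn = 0, glcm_inverse_variance = 0,
         glcm_max_probability = 0, glcm_sum_average = 0, glcm_sum_entropy = 0,
         glcm_sum_variance = 0, glcm_variance = 0)
  psum <- numeric(2 * L); pdif <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    mu2 <- i + j - mux - muy
    f["glcm_autocorrelation"] <- f["glcm_autocorrelation"] + i * j * p
    f["glcm_cluster_prominence"] <- f["glcm_cluster_prominence"] + mu2^4 * p
    f["glcm_cluster_shade"] <- f["glcm_cluster_shade"] + mu2^3 * p
    f["glcm_cluster_tendency"] <- f["glcm_cluster_tendency"] + mu2^2 * p
    f["glcm_contrast"] <- f["glcm_contrast"] + (i - j)^2 * p
    f["glcm_dissimilarity"] <- f["glcm_dissimilarity"] + abs(i - j) * p
    f["glcm_energy"] <- f["glcm_energy"] + p^2
    if (p > 0) f["glcm_entropy"] <- f["glcm_entropy"] - p * log2(p)
    f["glcm_homogeneity1"] <- f["glcm_homogeneity1"] + p / (1 + abs(i - j))
    f["glcm_homogeneity2"] <- f["glcm_homogeneity2"] + p / (1 + (i - j)^2)
    f["glcm_idmn"] <- f["glcm_idmn"] + p / (1 + (i - j)^2 / L^2)
    f["glcm_idn"] <- f["glcm_idn"] + p / (1 + abs(i - j) / L)
    if (i != j)
      f["glcm_inverse_variance"] <- f["glcm_inverse_variance"] + p / (i - j)^2
    f["glcm_max_probability"] <- max(f["glcm_max_probability"], p)
    f["glcm_variance"] <- f["glcm_variance"] + (i - mux)^2 * p
    psum[i + j] <- psum[i + j] + p
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p
  }
  f["glcm_correlation"] <- if (sdx > 0 && sdy > 0)
    (f[["glcm_autocorrelation"]] - mux * muy) / (sdx * sdy) else NA_real_
  SA <- 0
  for (k in 2:(2 * L)) SA <- SA + k * psum[k]
  f["glcm_sum_average"] <- SA
  for (k in 2:(2 * L)) {
    if (psum[k] > 0)
      f["glcm_sum_entropy"] <- f["glcm_sum_entropy"] - psum[k] * log2(psum[k])
    f["glcm_sum_variance"] <- f["glcm_sum_variance"] + (k - SA)^2 * psum[k]
  }
  for (k in 1:L) if (pdif[k] > 0)
    f["glcm_difference_entropy"] <- f["glcm_difference_entropy"] -
      pdif[k] * log2(pdif[k])
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  HY <- -sum(py[py > 0] * log2(py[py > 0]))
  HXY1 <- HXY2 <- 0
  for (i in 1:L) for (j in 1:L) {
    pp <- px[i] * py[j]
    if (pp > 0) {
      if (P[i, j] > 0) HXY1 <- HXY1 - P[i, j] * log2(pp)
      HXY2 <- HXY2 - pp * log2(pp)
    }
  }
  H <- f[["glcm_entropy"]]
  f["glcm_imc1"] <- if (max(HX, HY) > 0) (H - HXY1) / max(HX, HY) else NA_real_
  f["glcm_imc2"] <- sqrt(max(0, 1 - 2^(-2 * (HXY2 - H))))
  f
}

naive_glrlm_features <- function(R, n_voxels) {
  Nr <- sum(R)
  f <- c(glrlm_sre = 0, glrlm_lre = 0, glrlm_gln = 0, glrlm_rln = 0,
         glrlm_rp = Nr / n_voxels, glrlm_lglre = 0, glrlm_hglre = 0,
         glrlm_srlgle = 0, glrlm_srhgle = 0, glrlm_lrlgle = 0,
         glrlm_lrhgle = 0)
  for (g in seq_len(nrow(R))) for (r in seq_len(ncol(R))) {
    p <- R[g, r]
    f["glrlm_sre"] <- f["glrlm_sre"] + p / r^2
    f["glrlm_lre"] <- f["glrlm_lre"] + p * r^2
    f["glrlm_lglre"] <- f["glrlm_lglre"] + p / g^2
    f["glrlm_hglre"] <- f["glrlm_hglre"] + p * g^2
    f["glrlm_srlgle"] <- f["glrlm_srlgle"] + p / (g^2 * r^2)
    f["glrlm_srhgle"] <- f["glrlm_srhgle"] + p * g^2 / r^2
    f["glrlm_lrlgle"] <- f["glrlm_lrlgle"] + p * r^2 / g^2
    f["glrlm_lrhgle"] <- f["glrlm_lrhgle"] + p * g^2 * r^2
  }
  for (g in seq_len(nrow(R))) f["glrlm_gln"] <- f["glrlm_gln"] + sum(R[g, ])^2
  for (r in seq_len(ncol(R))) f["glrlm_rln"] <- f["glrlm_rln"] + sum(R[, r])^2
  sel <- !(names(f) %in% "glrlm_rp")
  f[sel] <- f[sel] / Nr
  f
}

# --- ANOVA / ICC oracles ----------------------------------------------------

naive_icc_twoway <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- sum(x) / (n * k)
  ssr <- 0
  for (i in 1:n) ssr <- ssr + k * (sum(x[i, ]) / k - gm)^2
  ssc <- 0
  for (j in 1:k) ssc <- ssc + n * (sum(x[, j]) / n - gm)^2
  sse <- 0
  for (i in 1:n) for (j in 1:k)
    sse <- sse + (x[i, j] - sum(x[i, ]) / k - sum(x[, j]) / n + gm)^2
  MSR <- ssr / (n - 1); MSC <- ssc / (k - 1); MSE <- sse / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

naive_icc_oneway <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- sum(x) / (n * k)
  ssr <- 0; ssw <- 0
  for (i in 1:n) {
    mi <- sum(x[i, ]) / k
    ssr <- ssr + k * (mi - gm)^2
    for (j in 1:k) ssw <- ssw + (x[i, j] - mi)^2
  }
  MSR <- ssr / (n - 1); MSW <- ssw / (n * (k - 1))
  (MSR - MSW) / (MSR + (k - 1) * MSW)
}

# --- convex hull oracle -----------------------------------------------------

# Exact membership test for integer points with affine rank 3: a point is in
# the hull iff it is on the inner side of every supporting plane spanned by
# a triple of the points.
in_hull_bf <- function(q, S) {
  m <- nrow(S)
  for (a in 1:(m - 2)) for (b in (a + 1):(m - 1)) for (cc in (b + 1):m) {
    u <- S[b, ] - S[a, ]; v <- S[cc, ] - S[a, ]
    n <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    if (all(n == 0)) next
    dots <- as.vector((S - matrix(S[a, ], m, 3, byrow = TRUE)) %*% n)
    dq <- sum((q - S[a, ]) * n)
    if (max(dots) <= 0 && dq > 0) return(FALSE)
    if (min(dots) >= 0 && dq < 0) return(FALSE)
  }
  TRUE
}

# --- misc -------------------------------------------------------------------

make_sphere_mask <- function(r_vox, n, spacing = c(1, 1, 1)) {
  cc <- ((seq_len(n) - 1) - (n - 1) / 2)
  X <- array(cc * spacing[1], c(n, n, n))
  Y <- aperm(array(cc * spacing[2], c(n, n, n)), c(2, 1, 3))
  Z <- aperm(array(cc * spacing[3], c(n, n, n)), c(3, 2, 1))
  seg_mask(sqrt(X^2 + Y^2 + Z^2) <= r_vox, spacing)
}

quiet_phantom <- function(seed = 1, ...) {
  generate_phantom(phantom_spec(seed = seed, ...))
}
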