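test_that("discretization follows the fixed-bin-width floor rule", {
  v <- array(c(0, 24, 25, 49, -5, 7, 99, 60), c(2, 2, 2))
  m <- array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), c(2, 2, 2))
  d <- discretize(v, m, 25)
  expect_equal(sort(unique(d$levels[m])), c(1L, 2L))
  expect_equal(d$levels[1, 1, 1], 1L)  # 0  -> level 1
  expect_equal(d$levels[2, 1, 1], 1L)  # 24 -> level 1
  expect_equal(d$levels[1, 2, 1], 2L)  # 25 -> level 2
  expect_equal(d$levels[2, 2, 1], 2L)  # 49 -> level 2
  expect_equal(d$L, 2L)
  expect_true(all(d$levels[!m] == 0L))
  # constant volume and huge bins both collapse to a single level
  expect_equal(discretize(array(7, c(2, 2, 2)), array(TRUE, c(2, 2, 2)), 25)$L, 1L)
  expect_equal(discretize(v, m, 1000)$L, 1L)
  expect_error(discretize(v, array(FALSE, c(2, 2, 2)), 25), "empty")
  expect_error(discretize(v, m, 0), "bin_width")
})

test_that("first-order features match hand-computed values", {
  v <- array(c(0, 0, 100, 100, 0, 0, 0, 0), c(2, 2, 2))
  m <- array(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), c(2, 2, 2))
  f <- intensity_features(v, m, bin_width = 25)
  expect_equal(unname(f["intensity_mean"]), 50)
  expect_equal(unname(f["intensity_range"]), 100)
  expect_equal(unname(f["intensity_variance"]), 2500)  # population
  expect_equal(unname(f["intensity_rms"]), sqrt(5000), tolerance = 1e-12)
  expect_equal(unname(f["intensity_skewness"]), 0)
  expect_equal(unname(f["intensity_entropy"]), 1)      # two equal bins, bits
  expect_equal(unname(f["intensity_uniformity"]), 0.5)
  expect_equal(unname(f["intensity_energy"]), 20000)
  expect_equal(unname(f["intensity_mad"]), 50)
  # constant input
  fc <- intensity_features(array(3, c(2, 2, 1) * c(1, 1, 2)),
                           array(TRUE, c(2, 2, 2)))
  expect_equal(unname(fc["intensity_variance"]), 0)
  expect_equal(unname(fc["intensity_entropy"]), 0)
  expect_equal(unname(fc["intensity_uniformity"]), 1)
  expect_true(is.na(fc["intensity_skewness"]))
})

test_that("first-order features respect order statistics on random input", {
  for (r in 1:5) {
    set.seed(r)
    v <- array(rnorm(4^3, sd = 50), c(4, 4, 4))
    m <- array(runif(4^3) < 0.7, c(4, 4, 4))
    if (!any(m)) next
    f <- intensity_features(v, m)
    expect_lte(f[["intensity_min"]], f[["intensity_median"]])
    expect_lte(f[["intensity_median"]], f[["intensity_max"]])
    expect_equal(f[["intensity_range"]],
                 f[["intensity_max"]] - f[["intensity_min"]])
    expect_equal(f[["intensity_sd"]]^2, f[["intensity_variance"]])
  }
})

test_that("moment features agree with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(3)
  v <- array(rnorm(6^3, 100, 40), c(6, 6, 6))
  m <- array(TRUE, c(6, 6, 6))
  f <- intensity_features(v, m)
  x <- as.numeric(v)
  expect_equal(f[["intensity_skewness"]], e1071::skewness(x, type = 1),
               tolerance = 1e-12)
  expect_equal(f[["intensity_kurtosis"]], e1071::kurtosis(x, type = 1) + 3,
               tolerance = 1e-12)
})

test_that("shape features are exact on a cube and consistent on a sphere", {
  m <- seg_mask(array(FALSE, c(10, 10, 10)))
  m[4:7, 4:7, 4:7] <- TRUE
  f <- shape_features(m)
  expect_equal(unname(f["shape_volume"]), 64)
  expect_equal(unname(f["shape_max_diameter"]), sqrt(27), tolerance = 1e-12)
  # voxel-face area of a 4^3 cube: 6 faces x 16
  fv <- shape_features(m, area_mode = "voxel")
  expect_equal(unname(fv["shape_surface_area"]), 96)
  # digitized sphere approaches the analytic limits
  sm <- make_sphere_mask(12, 33)
  fs <- shape_features(sm)
  expect_lt(abs(fs[["shape_sphericity"]] - 1), 0.03)
  expect_lt(abs(fs[["shape_compactness2"]] - 1), 0.10)
  expect_lt(abs(fs[["shape_spherical_disproportion"]] - 1), 0.03)
  expect_equal(fs[["shape_max_diameter"]], 24, tolerance = 0.1)
  # internal consistency of the derived descriptors
  A <- fs[["shape_surface_area"]]; V <- fs[["shape_volume"]]
  expect_equal(fs[["shape_surface_to_volume"]], A / V)
  expect_equal(fs[["shape_compactness2"]], 36 * pi * V^2 / A^3)
})

test_that("the direction set is the half 26-neighborhood", {
  dirs <- direction_set()
  expect_equal(nrow(dirs), 13)
  expect_true(all(apply(abs(dirs), 1, max) == 1))
  # no vector is another's negation, and dirs plus -dirs = 26 neighbors
  full <- rbind(dirs, -dirs)
  expect_equal(nrow(unique(full)), 26)
})

test_that("co-occurrence and run-length matrices match the spec examples", {
  lev <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))  # columns along axis 2
  disc <- as_disc(lev)
  # along axis 2 every pair is (1,2): symmetric probabilities 0.5 / 0.5
  P <- glc_matrix(disc, c(0L, 1L, 0L))
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[2, 1], 0.5)
  expect_equal(sum(P), 1)
  # along axis 1 pairs are (1,1) and (2,2)
  P1 <- glc_matrix(disc, c(1L, 0L, 0L))
  expect_equal(P1[1, 1], 0.5); expect_equal(P1[2, 2], 0.5)
  # constant grid: single diagonal entry
  Pc <- glc_matrix(as_disc(array(1L, c(3, 3, 1))), c(1L, 0L, 0L))
  expect_equal(Pc[1, 1], 1)
  # masking: an out-of-mask endpoint contributes nothing
  lev2 <- array(c(1L, 0L, 1L, 1L), c(4, 1, 1))
  P2 <- glc_matrix(as_disc(lev2, L = 1L), c(1L, 0L, 0L), normalize = FALSE)
  expect_equal(P2[1, 1], 2)  # only the (3,4) pair, counted both ways
  # run lengths
  R <- glrl_matrix(as_disc(array(3L, c(4, 1, 1)), L = 3L), c(1L, 0L, 0L))
  expect_equal(R[3, 4], 1)
  expect_equal(sum(R), 1)
  R2 <- glrl_matrix(as_disc(array(c(1L, 2L, 1L, 2L), c(4, 1, 1)), L = 2L),
                    c(1L, 0L, 0L))
  expect_equal(sum(R2[, 1]), 4)
  expect_equal(sum(R2), 4)
})

test_that("GLCM features match hand computation on the two-level example", {
  P <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  f <- glcm_features(P)
  expect_equal(unname(f["glcm_contrast"]), 1)
  expect_equal(unname(f["glcm_energy"]), 0.5)
  expect_equal(unname(f["glcm_entropy"]), 1)
  expect_equal(unname(f["glcm_max_probability"]), 0.5)
  expect_equal(unname(f["glcm_dissimilarity"]), 1)
  expect_equal(unname(f["glcm_sum_average"]), 3)
  # single diagonal entry
  f2 <- glcm_features(matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(unname(f2["glcm_contrast"]), 0)
  expect_equal(unname(f2["glcm_energy"]), 1)
  expect_equal(unname(f2["glcm_entropy"]), 0)
  expect_true(is.na(f2["glcm_correlation"]))  # zero marginal variance
})

test_that("GLCM feature bounds hold on random matrices", {
  set.seed(11)
  for (r in 1:20) {
    L <- sample(2:5, 1)
    M <- matrix(runif(L * L), L, L)
    M <- (M + t(M)); M <- M / sum(M)
    f <- glcm_features(M)
    expect_gt(f[["glcm_energy"]], 0); expect_lte(f[["glcm_energy"]], 1)
    expect_gte(f[["glcm_entropy"]], 0)
    expect_gte(f[["glcm_contrast"]], 0)
    expect_gte(f[["glcm_homogeneity1"]], 0)
    expect_lte(f[["glcm_imc2"]], 1)
  }
})

test_that("GLRLM features match the single-run example and Jensen ordering", {
  R <- matrix(0, 3, 4); R[3, 4] <- 1
  f <- glrlm_features(R, n_voxels = 16)
  expect_equal(unname(f["glrlm_sre"]), 1 / 16)
  expect_equal(unname(f["glrlm_lre"]), 16)
  expect_equal(unname(f["glrlm_rp"]), 1 / 16 * 1)  # 1 run / 16 voxels
  expect_equal(unname(f["glrlm_hglre"]), 9)
  # all runs length 1
  R1 <- matrix(0, 2, 3); R1[1, 1] <- 3; R1[2, 1] <- 2
  f1 <- glrlm_features(R1, n_voxels = 5)
  expect_equal(unname(f1["glrlm_sre"]), 1)
  expect_equal(unname(f1["glrlm_lre"]), 1)
  # SRE <= 1 <= LRE whenever runs of length > 1 exist
  set.seed(5)
  for (r in 1:20) {
    RR <- matrix(rpois(12, 1), 3, 4)
    if (sum(RR[, -1]) == 0 || sum(RR) == 0) next
    fr <- glrlm_features(RR, n_voxels = sum(RR %*% (1:4)))
    expect_lte(fr[["glrlm_sre"]], 1)
    expect_gte(fr[["glrlm_lre"]], 1)
  }
})

test_that("matrix builders agree with naive triple-loop oracles", {
  set.seed(21)
  dirs <- direction_set()
  for (r in 1:10) {
    lev <- random_levels(c(6, 6, 6), L = 4)
    if (!any(lev > 0)) next
    disc <- as_disc(lev, L = 4L)
    for (k in sample(nrow(dirs), 4)) {
      dir <- dirs[k, ]
      expect_equal(glc_matrix(disc, dir, normalize = FALSE),
                   naive_glcm(lev, dir, 4), tolerance = 1e-12)
      Rpkg <- glrl_matrix(disc, dir)
      Rnv <- naive_glrlm(lev, dir, 4)
      nc <- max(ncol(Rpkg), ncol(Rnv))
      pad <- function(M) cbind(M, matrix(0, nrow(M), nc - ncol(M)))
      expect_equal(pad(Rpkg), pad(Rnv), tolerance = 1e-12)
      # conservation: sum over entries x run length = traversed voxels
      expect_equal(sum(Rpkg %*% seq_len(ncol(Rpkg))), sum(lev > 0))
    }
  }
})

test_that("direction averaging equals the per-direction mean", {
  set.seed(31)
  lev <- random_levels(c(6, 6, 6), L = 3)
  disc <- as_disc(lev, L = 3L)
  tf <- texture_features(disc)
  expect_length(tf, 33)
  dirs <- direction_set()
  per <- sapply(seq_len(nrow(dirs)), function(k) {
    c(glcm_features(glc_matrix(disc, dirs[k, ])),
      glrlm_features(glrl_matrix(disc, dirs[k, ]), sum(lev > 0)))
  })
  expect_equal(unname(tf), unname(rowMeans(per, na.rm = TRUE)),
               tolerance = 1e-12)
  # isotropy: on a constant texture all directions agree with the mean
  lev_c <- array(0L, c(5, 5, 5)); lev_c[2:4, 2:4, 2:4] <- 1L
  disc_c <- as_disc(lev_c, L = 1L)
  tf_c <- texture_features(disc_c)
  one_dir <- c(glcm_features(glc_matrix(disc_c, c(1L, 0L, 0L))),
               glrlm_features(glrl_matrix(disc_c, c(1L, 0L, 0L)),
                              sum(lev_c > 0)))
  expect_equal(tf_c[["glcm_energy"]], one_dir[["glcm_energy"]])
})

test_that("the full panel is complete, finite, and geometrically invariant", {
  ph <- quiet_phantom(seed = 13)
  fv <- extract_features(ph$volume, ph$mask)
  expect_length(fv, 56)
  expect_named(fv, feature_names())
  expect_true(all(is.finite(fv)))
  fam <- feature_families()
  expect_equal(sum(fam == "intensity"), 15)
  expect_equal(sum(fam == "shape"), 8)
  expect_equal(sum(fam == "texture"), 33)
  # whole-voxel translation leaves every feature unchanged
  shift <- function(a, k) {
    d <- dim(a); out <- array(a[1] * 0, d)
    out[(1 + k):d[1], , ] <- a[1:(d[1] - k), , ]
    out
  }
  voln <- as_array_np(ph$volume); mskn <- as_array_np(ph$mask)
  vol2 <- image_volume(shift(voln, 2), spacing(ph$volume))
  msk2 <- seg_mask(shift(mskn, 2), spacing(ph$mask))
  fv2 <- extract_features(vol2, msk2)
  expect_equal(fv2, fv, tolerance = 1e-10)
})

test_that("texture features are invariant under axis permutation at isotropic spacing", {
  set.seed(41)
  v <- array(rnorm(8^3, 0, 50), c(8, 8, 8))
  m <- array(FALSE, c(8, 8, 8)); m[2:7, 2:7, 2:7] <- TRUE
  m[3, 3, 3] <- FALSE
  d1 <- discretize(v, m, 25)
  d2 <- discretize(aperm(v, c(2, 3, 1)), aperm(m, c(2, 3, 1)), 25)
  expect_equal(texture_features(d1), texture_features(d2), tolerance = 1e-10)
})
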