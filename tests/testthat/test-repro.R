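test_that("rank-sum test reproduces the exact enumeration example", {
  r <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_equal(r$statistic, 0)  # W of x against y
  # identical multisets are maximally non-significant
  expect_equal(wilcoxon_ranksum(c(2, 2, 5), c(5, 2, 2))$p_value, 1)
  expect_equal(wilcoxon_ranksum(rep(3, 4), rep(3, 5))$p_value, 1)
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum p-values agree with a permutation oracle", {
  set.seed(202)
  for (rep_i in 1:3) {
    x <- rnorm(8); y <- rnorm(8, mean = 0.8)
    got <- wilcoxon_ranksum(x, y)$p_value
    # Monte-Carlo permutation null of the rank-sum statistic
    pooled <- c(x, y)
    rk <- rank(pooled)
    obs <- sum(rk[1:8]) - 8 * 9 / 2
    n_perm <- 20000
    perm <- replicate(n_perm, {
      idx <- sample.int(16, 8)
      sum(rk[idx]) - 8 * 9 / 2
    })
    mu <- 8 * 8 / 2
    p_mc <- mean(abs(perm - mu) >= abs(obs - mu) - 1e-9)
    expect_lt(abs(got - p_mc), 0.015)
  }
})

test_that("Z-normalization has the documented moments and containment behavior", {
  # synthetic 11-observer feature table for 3 tumors, one feature
  set.seed(7)
  rows <- expand.grid(observer = 1:6, tumor = 1:3)
  feat <- data.frame(tumor = rep(1:3, each = 11),
                     group = rep(c(rep("manual", 5), rep("semiauto", 6)), 3),
                     observer = rep(c(1:5, 1, 1, 2, 2, 3, 3), 3),
                     run = rep(c(rep(1, 5), 1, 2, 1, 2, 1, 2), 3))
  # manual values spread wide, semiauto narrow, around a per-tumor center
  center <- rep(c(10, 20, 30), each = 11)
  spread <- ifelse(feat$group == "manual", 4, 1)
  feat$intensity_mean <- center + spread * rep(c(-1, -0.5, 0, 0.5, 1,
                                                 -0.5, -0.3, 0, 0.1, 0.3, 0.5), 3)
  rs <- znormalize_and_range(feat)
  man <- rs$per_feature[rs$per_feature$group == "manual", ]
  sa <- rs$per_feature[rs$per_feature$group == "semiauto", ]
  expect_gt(man$range, sa$range)      # wide manual spread survives z-scoring
  expect_lt(man$lower, sa$lower)      # semiauto contained in manual range
  expect_gt(man$upper, sa$upper)
  # z-scores per tumor have mean 0 and sd 1
  z <- (feat$intensity_mean[1:11] - mean(feat$intensity_mean[1:11])) /
    sd(feat$intensity_mean[1:11])
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("range statistics match a naive recomputation oracle", {
  set.seed(31)
  n_t <- 4
  feat <- data.frame(tumor = rep(1:n_t, each = 11),
                     group = rep(c(rep("manual", 5), rep("semiauto", 6)), n_t),
                     observer = rep(c(1:5, 1, 1, 2, 2, 3, 3), n_t),
                     run = rep(c(rep(1, 5), 1, 2, 1, 2, 1, 2), n_t))
  feat$glcm_contrast <- rnorm(nrow(feat), rep(rnorm(n_t, 10, 4), each = 11))
  rs <- znormalize_and_range(feat)
  # naive recomputation
  for (grp in c("manual", "semiauto")) {
    ranges <- lows <- numeric(n_t)
    for (t in 1:n_t) {
      v <- feat$glcm_contrast[feat$tumor == t]
      z <- (v - mean(v)) / sd(v)
      zg <- z[feat$group[feat$tumor == t] == grp]
      ranges[t] <- max(zg) - min(zg)
      lows[t] <- min(zg)
    }
    row <- rs$per_feature[rs$per_feature$group == grp, ]
    expect_equal(row$range, mean(ranges), tolerance = 1e-12)
    expect_equal(row$lower, mean(lows), tolerance = 1e-12)
  }
})

test_that("zero-spread tumor-feature cells get zero z-scores, flagged", {
  feat <- data.frame(tumor = rep(1, 11),
                     group = c(rep("manual", 5), rep("semiauto", 6)),
                     observer = c(1:5, 1, 1, 2, 2, 3, 3),
                     run = c(rep(1, 5), 1, 2, 1, 2, 1, 2),
                     shape_volume = rep(42, 11))
  rs <- znormalize_and_range(feat)
  expect_equal(rs$n_zero_sd, 1L)
  expect_true(all(rs$per_feature$range == 0))
})

test_that("per-feature ICC tables cover all features and match a naive loop", {
  set.seed(99)
  n_t <- 6
  ids <- data.frame(tumor = rep(1:n_t, each = 11),
                    group = rep(c(rep("manual", 5), rep("semiauto", 6)), n_t),
                    observer = rep(c(1:5, 1, 1, 2, 2, 3, 3), n_t),
                    run = rep(c(rep(1, 5), 1, 2, 1, 2, 1, 2), n_t))
  feat <- cbind(ids, as.data.frame(stats::setNames(
    lapply(feature_names(), function(f)
      rnorm(nrow(ids), rep(rnorm(n_t, 0, 2), each = 11))),
    feature_names())))
  cols <- data.frame(group = "manual", observer = 1:5, run = 1)
  tab <- icc_per_feature(feat, cols, model = "twoway")
  expect_equal(nrow(tab), 56)
  expect_setequal(tab$feature, feature_names())
  # naive per-feature loop oracle on a couple of features
  for (fn in c("intensity_mean", "glrlm_sre", "shape_sphericity")) {
    mat <- sapply(1:5, function(o)
      sapply(1:n_t, function(t)
        feat[[fn]][feat$tumor == t & feat$group == "manual" &
                   feat$observer == o]))
    expect_equal(tab$icc_raw[tab$feature == fn], naive_icc_twoway(mat),
                 tolerance = 1e-10)
  }
  # duplicated observer columns give perfect agreement
  featd <- feat
  for (o in 2:5) {
    sel <- featd$group == "manual" & featd$observer == o
    base <- featd$group == "manual" & featd$observer == 1
    featd[sel, feature_names()] <- featd[base, feature_names()]
  }
  tabd <- icc_per_feature(featd, cols, model = "twoway")
  expect_true(all(tabd$icc == 1))
})

test_that("undefined feature values drop subjects row-wise with bookkeeping", {
  n_t <- 5
  ids <- data.frame(tumor = rep(1:n_t, each = 5),
                    group = "manual",
                    observer = rep(1:5, n_t), run = 1)
  set.seed(1)
  feat <- cbind(ids, as.data.frame(stats::setNames(
    lapply(feature_names(), function(f)
      rnorm(nrow(ids), rep(1:n_t, each = 5))), feature_names())))
  feat$glcm_imc1[feat$tumor == 3 & feat$observer == 2] <- NA
  tab <- icc_per_feature(feat, data.frame(group = "manual", observer = 1:5,
                                          run = 1))
  expect_equal(tab$n_dropped[tab$feature == "glcm_imc1"], 1L)
  expect_equal(tab$n[tab$feature == "glcm_imc1"], n_t - 1L)
  expect_equal(tab$n_dropped[tab$feature == "intensity_mean"], 0L)
})

test_that("ICC summaries give mean +/- SD overall and per family", {
  tab <- data.frame(feature = feature_names(),
                    icc = rep(c(0.9, 0.7, 0.6), length.out = 56),
                    stringsAsFactors = FALSE)
  s <- summarize_icc(tab)
  expect_equal(s$set, c("all", "intensity", "shape", "texture"))
  expect_equal(s$n, c(56, 15, 8, 33))
  expect_equal(s$mean[1], mean(tab$icc), tolerance = 1e-12)
  fam <- feature_families()
  expect_equal(s$mean[3], mean(tab$icc[fam[tab$feature] == "shape"]),
               tolerance = 1e-12)
  # single-ICC edge case
  s1 <- summarize_icc(data.frame(feature = "intensity_mean", icc = 0.7))
  expect_equal(s1$mean[1], 0.7)
  expect_equal(s1$sd[1], 0)
})
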