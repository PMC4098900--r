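# Feature-wise reproducibility analysis: ICC per feature and observer set,
# rank-sum group comparisons, and Z-score normalized range statistics.

# Build the subjects x raters matrix for one feature from the long-format
# study feature table. `columns` is a data frame with `group`, `observer`,
# `run` rows selecting the raters.
ratings_matrix <- function(features, feature, columns) {
  n_t <- sort(unique(features$tumor))
  mat <- vapply(seq_len(nrow(columns)), function(ci) {
    sel <- features$group == columns$group[ci] &
      features$observer == columns$observer[ci] &
      features$run == columns$run[ci]
    sub <- features[sel, c("tumor", feature)]
    as.numeric(sub[[feature]][match(n_t, sub$tumor)])
  }, numeric(length(n_t)))
  mat <- matrix(mat, nrow = length(n_t),
                dimnames = list(n_t, NULL))
  mat
}

# Observer-set definitions used by the canonical design:
#  manual       : the 5 manual observers (two-way mixed absolute ICC)
#  semiauto_set1: run 1 of each semiauto observer (two-way mixed absolute)
#  semiauto_set2: run 2 of each semiauto observer (two-way mixed absolute)
#  intra_o<i>   : the 2 runs of semiauto observer i (one-way ICC)
observer_sets <- function(features) {
  man_obs <- sort(unique(features$observer[features$group == "manual"]))
  sa_obs <- sort(unique(features$observer[features$group == "semiauto"]))
  sa_runs <- sort(unique(features$run[features$group == "semiauto"]))
  sets <- list(
    manual = list(model = "twoway",
                  columns = data.frame(group = "manual", observer = man_obs,
                                       run = 1L)))
  for (rr in sa_runs) {
    sets[[sprintf("semiauto_set%d", rr)]] <-
      list(model = "twoway",
           columns = data.frame(group = "semiauto", observer = sa_obs, run = rr))
  }
  if (length(sa_runs) >= 2L) {
    for (o in sa_obs) {
      sets[[sprintf("intra_o%d", o)]] <-
        list(model = "oneway",
             columns = data.frame(group = "semiauto", observer = o, run = sa_runs))
    }
  }
  sets
}

#' Per-feature ICC for an observer set
#'
#' Builds one subjects-by-raters matrix per feature (subjects = tumors,
#' raters = the selected observers/runs) and applies the matching ICC
#' estimator: two-way mixed absolute agreement for inter-observer sets,
#' one-way for intra-observer run pairs. Tumors with an undefined feature
#' value are dropped row-wise (count recorded in the result).
#'
#' @param features study feature data frame ([extract_study_features()]).
#' @param columns data frame with columns `group`, `observer`, `run`
#'   selecting the raters (one row per rater).
#' @param model `"twoway"` (mixed, absolute agreement) or `"oneway"`.
#' @return data frame with one row per feature: `feature`, `icc`,
#'   `icc_raw`, `model`, `n`, `k`, `n_dropped`, `class`.
#' @export
icc_per_feature <- function(features, columns, model = c("twoway", "oneway")) {
  model <- match.arg(model)
  if (nrow(columns) < 2L) stopf("an observer set needs >= 2 raters")
  fns <- intersect(feature_names(), names(features))
  if (length(fns) == 0L) stopf("no feature columns found")
  rows <- lapply(fns, function(fn) {
    mat <- ratings_matrix(features, fn, columns)
    complete <- stats::complete.cases(mat)
    res <- if (sum(complete) >= 2L) {
      if (model == "twoway") icc_twoway_mixed_absolute(mat[complete, , drop = FALSE])
      else icc_oneway(mat[complete, , drop = FALSE])
    } else icc_result(NA_real_, model, sum(complete), ncol(mat), NA_real_)
    data.frame(feature = fn, icc = res$icc, icc_raw = res$icc_raw,
               model = res$model, n = res$n, k = res$k,
               n_dropped = sum(!complete),
               class = as.character(classify_icc(res)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum comparison
#'
#' Two-sample rank-sum test: exact enumeration for small samples without
#' ties, normal approximation with tie correction otherwise. Returns `p = 1`
#' when every value in both groups is identical.
#'
#' @param x,y numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with `statistic` (rank-sum W of `x`) and `p_value`.
#' @export
wilcoxon_ranksum <- function(x, y, alternative = "two.sided") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  ties <- any(duplicated(c(x, y)))
  use_exact <- !ties && (length(x) + length(y)) <= 20L
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = use_exact,
    correct = !use_exact))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = min(p, 1))
}

#' Z-score normalized feature ranges per observer group
#'
#' For every (tumor, feature) cell the 11 observer values (5 manual + 6
#' semi-auto by default) are Z-score normalized together; per group the
#' minimum, maximum and range of the normalized values are recorded. Group
#' comparisons (range, lower bound, upper bound) aggregate the per-tumor
#' statistics over tumors (mean) and compare the two groups across features
#' with [wilcoxon_ranksum()].
#'
#' @param features study feature data frame.
#' @param mode `"per_tumor"` (default: Z-scores within each tumor-feature
#'   cell over its 11 values) or `"pooled"` (Z-scores per feature over all
#'   tumor-observer values).
#' @return a `range_stats` list: `per_feature` data frame (feature, group,
#'   mean range/lower/upper over tumors), `tests` (p-values for range and
#'   bounds), `mode`, `n_zero_sd` (cells with zero spread, Z defined as 0).
#' @export
znormalize_and_range <- function(features, mode = c("per_tumor", "pooled")) {
  mode <- match.arg(mode)
  fns <- intersect(feature_names(), names(features))
  groups <- c("manual", "semiauto")
  tumors <- sort(unique(features$tumor))
  n_zero_sd <- 0L
  per_feature <- list()
  for (fn in fns) {
    stat <- list()
    if (mode == "pooled") {
      v_all <- features[[fn]]
      mu <- mean(v_all, na.rm = TRUE); s <- sd(v_all, na.rm = TRUE)
    }
    gr_range <- gr_lo <- gr_hi <- matrix(NA_real_, length(tumors), 2,
                                         dimnames = list(NULL, groups))
    for (ti in seq_along(tumors)) {
      sel_t <- features$tumor == tumors[ti]
      v <- features[[fn]][sel_t]
      if (mode == "per_tumor") {
        mu <- mean(v, na.rm = TRUE); s <- sd(v, na.rm = TRUE)
      }
      if (is.na(s) || s == 0) {
        z <- rep(0, length(v))   # flagged: no spread across segmentations
        n_zero_sd <- n_zero_sd + 1L
      } else z <- (v - mu) / s
      for (gi in seq_along(groups)) {
        zg <- z[features$group[sel_t] == groups[gi]]
        zg <- zg[!is.na(zg)]
        if (length(zg)) {
          gr_range[ti, gi] <- max(zg) - min(zg)
          gr_lo[ti, gi] <- min(zg)
          gr_hi[ti, gi] <- max(zg)
        }
      }
    }
    for (gi in seq_along(groups)) {
      per_feature[[length(per_feature) + 1L]] <- data.frame(
        feature = fn, group = groups[gi],
        range = mean(gr_range[, gi], na.rm = TRUE),
        lower = mean(gr_lo[, gi], na.rm = TRUE),
        upper = mean(gr_hi[, gi], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  pf <- do.call(rbind, per_feature)
  man <- pf[pf$group == "manual", ]
  sa <- pf[pf$group == "semiauto", ]
  tests <- list(
    range = wilcoxon_ranksum(man$range, sa$range),
    lower = wilcoxon_ranksum(man$lower, sa$lower),
    upper = wilcoxon_ranksum(man$upper, sa$upper))
  structure(list(per_feature = pf, tests = tests, mode = mode,
                 n_zero_sd = n_zero_sd),
            class = "range_stats")
}

#' @export
print.range_stats <- function(x, ...) {
  cat(sprintf("<range_stats> mode = %s\n", x$mode))
  cat(sprintf("  normalized range : manual %.3f vs semiauto %.3f (p = %.3g)\n",
              mean(x$per_feature$range[x$per_feature$group == "manual"]),
              mean(x$per_feature$range[x$per_feature$group == "semiauto"]),
              x$tests$range$p_value))
  cat(sprintf("  lower bound p = %.3g, upper bound p = %.3g\n",
              x$tests$lower$p_value, x$tests$upper$p_value))
  invisible(x)
}

#' Mean +/- SD summaries of per-feature ICCs
#'
#' @param icc_table data frame from [icc_per_feature()].
#' @param families optional named family vector ([feature_families()]).
#' @return data frame with rows `all`, `intensity`, `shape`, `texture`:
#'   mean, SD and count of defined ICCs.
#' @export
summarize_icc <- function(icc_table, families = feature_families()) {
  fam <- families[icc_table$feature]
  summarize_one <- function(sel, label) {
    v <- icc_table$icc[sel]
    v <- v[!is.na(v)]
    data.frame(set = label, mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
               n = length(v), stringsAsFactors = FALSE)
  }
  out <- rbind(summarize_one(rep(TRUE, nrow(icc_table)), "all"),
               summarize_one(fam == "intensity", "intensity"),
               summarize_one(fam == "shape", "shape"),
               summarize_one(fam == "texture", "texture"))
  rownames(out) <- NULL
  out
}
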