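# Intraclass correlation coefficients from ANOVA mean squares.
#
# Two estimators are provided, matching the two study designs:
#  * inter-observer agreement: two-way mixed-effects model, absolute
#    agreement, single rater (McGraw & Wong case 3A):
#      ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))
#  * intra-observer (repeated runs): one-way random-effects model (case 1):
#      ICC = (MSR - MSW) / (MSR + (k-1) MSW)
# with MSR = between-subjects, MSC = between-raters, MSE = residual and
# MSW = within-subjects mean squares. Raw estimates can be negative; they
# are preserved in the result and clamped to [0, 1] for classification.

icc_result <- function(icc_raw, model, n, k, MSR, MSC = NA_real_,
                       MSE = NA_real_, MSW = NA_real_) {
  structure(list(icc = if (is.na(icc_raw)) NA_real_ else min(max(icc_raw, 0), 1),
                 icc_raw = icc_raw, model = model, n = n, k = k,
                 MSR = MSR, MSC = MSC, MSE = MSE, MSW = MSW),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %s (%s; n = %d subjects, k = %d raters)\n",
              if (is.na(x$icc)) "undefined" else sprintf("%.4f", x$icc),
              x$model, x$n, x$k))
  invisible(x)
}

check_ratings <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (!is.numeric(ratings)) stopf("ratings must be numeric")
  ratings <- ratings[stats::complete.cases(ratings), , drop = FALSE]
  if (nrow(ratings) < 2L || ncol(ratings) < 2L)
    stopf("ratings need >= 2 subjects (rows) and >= 2 raters (columns); got %dx%d",
          nrow(ratings), ncol(ratings))
  if (any(!is.finite(ratings))) stopf("ratings must be finite")
  ratings
}

#' Intraclass correlation, two-way mixed model, absolute agreement
#'
#' Single-rater absolute-agreement ICC from the two-way (subjects x raters,
#' no replication) ANOVA decomposition. Used for inter-observer sets.
#'
#' @param ratings n x k numeric matrix: rows = subjects, columns = raters.
#'   Rows containing missing values are dropped.
#' @return an `icc_result` with the (clamped) `icc`, the raw estimate, and
#'   the mean squares `MSR`, `MSC`, `MSE`. When all entries are identical
#'   the ICC is undefined (`NA`) with diagnostics retained.
#' @examples
#' icc_twoway_mixed_absolute(matrix(c(1, 3, 5, 2, 4, 6), ncol = 2))  # 8/9
#' @export
icc_twoway_mixed_absolute <- function(ratings) {
  x <- check_ratings(ratings)
  n <- nrow(x); k <- ncol(x)
  m <- mean(x)
  rm_ <- rowMeans(x); cm_ <- colMeans(x)
  MSR <- k * sum((rm_ - m)^2) / (n - 1)
  MSC <- n * sum((cm_ - m)^2) / (k - 1)
  resid <- x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + m
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  raw <- if (abs(denom) < 1e-300) NA_real_ else (MSR - MSE) / denom
  icc_result(raw, "twoway_mixed_absolute", n, k, MSR, MSC = MSC, MSE = MSE)
}

#' Intraclass correlation, one-way random model
#'
#' Single-rater ICC from the one-way ANOVA decomposition (subjects random,
#' raters nested). Used for intra-observer run pairs.
#'
#' @inheritParams icc_twoway_mixed_absolute
#' @return an `icc_result` with mean squares `MSR` and `MSW`.
#' @examples
#' icc_oneway(matrix(c(1, 3, 5, 2, 4, 6), ncol = 2))  # 7.5/8.5
#' @export
icc_oneway <- function(ratings) {
  x <- check_ratings(ratings)
  n <- nrow(x); k <- ncol(x)
  m <- mean(x)
  rm_ <- rowMeans(x)
  MSR <- k * sum((rm_ - m)^2) / (n - 1)
  MSW <- sum((x - rm_)^2) / (n * (k - 1))
  denom <- MSR + (k - 1) * MSW
  raw <- if (abs(denom) < 1e-300) NA_real_ else (MSR - MSW) / denom
  icc_result(raw, "oneway", n, k, MSR, MSW = MSW)
}

#' Reproducibility class of an ICC value
#'
#' `high` for ICC >= 0.8, `medium` for 0.8 > ICC >= 0.5, `low` for
#' ICC < 0.5; undefined ICCs are `unclassified`. Negative raw estimates are
#' clamped to 0 first.
#'
#' @param icc an `icc_result` or numeric value.
#' @return factor level among `high`, `medium`, `low`, `unclassified`.
#' @export
classify_icc <- function(icc) {
  v <- if (inherits(icc, "icc_result")) icc$icc else icc
  lv <- c("high", "medium", "low", "unclassified")
  out <- vapply(v, function(vi) {
    if (is.na(vi)) return("unclassified")
    vi <- min(max(vi, 0), 1)
    if (vi >= 0.8) "high" else if (vi >= 0.5) "medium" else "low"
  }, character(1))
  factor(out, levels = lv)
}
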