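# Feature robustness within an investigation group: mean within-region
# percentage coefficient of variation across regions, plus a two-way
# absolute-agreement single-measurement intraclass correlation with regions
# as subjects and parameter levels as repeated measurements. A feature is
# robust when CV_mean < 10% and ICC > 0.90.

#' Within-region percentage coefficient of variation
#'
#' `100 * sd(values) / |mean(values)|` over the parameter levels of one
#' region. When the mean is negligible relative to the spread (features such
#' as skewness cross zero), the percentage is meaningless and the value is
#' returned as `NA` with attribute `flag = "near-zero-mean"`.
#'
#' @param values Feature values across the levels of a group (length >= 2).
#' @param eps Relative near-zero-mean guard: flagged when
#'   `|mean| < eps * sd`.
#' @return CV in percent, or flagged `NA`.
#' @examples
#' cv_per_region(c(1, 2, 3))  # 50
#' @export
cv_per_region <- function(values, eps = 1e-8) {
  if (length(values) < 2) rr_abort("CV needs at least 2 levels")
  if (any(!is.finite(values))) rr_abort("CV input must be finite")
  s <- stats::sd(values)
  m <- mean(values)
  if (abs(m) < eps * max(s, .Machine$double.eps)) {
    return(structure(NA_real_, flag = "near-zero-mean"))
  }
  100 * s / abs(m)
}

#' Mean CV across regions
#'
#' Arithmetic mean of the per-region CVs, dropping flagged (near-zero-mean)
#' regions. With no surviving region the feature is unassessable and `NA` is
#' returned with attribute `flag`.
#'
#' @param cvs Numeric vector of per-region CVs (possibly with `NA` flags).
#' @return CV_mean in percent.
#' @examples
#' cv_mean(c(10, 20, 30))  # 20
#' @export
cv_mean <- function(cvs) {
  ok <- is.finite(cvs)
  if (!any(ok)) {
    return(structure(NA_real_, flag = "unassessable", n_dropped = sum(!ok)))
  }
  structure(mean(cvs[ok]), n_dropped = sum(!ok))
}

#' Two-way absolute-agreement single-measurement ICC
#'
#' Intraclass correlation for agreement under a two-way model with regions
#' as rows (subjects) and parameter levels as columns (measurements),
#' single-measurement form:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`
#' with `MSR`, `MSC`, `MSE` the row, column and error mean squares of the
#' two-way layout (McGraw-Wong ICC(A,1)). Negative estimates are reported as
#' computed. A constant matrix has no subject variance to agree on and
#' returns flagged `NA`.
#'
#' @param m Numeric matrix, regions x levels, complete.
#' @return ICC in `[-1, 1]`, or flagged `NA` for degenerate input.
#' @examples
#' icc_agreement(matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5), nrow = 3))
#' @export
icc_agreement <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (anyNA(m)) {
    rr_abort("ICC needs a complete regions x levels matrix; run filter_invalid() first")
  }
  n <- nrow(m)  # regions
  k <- ncol(m)  # levels
  if (n < 2 || k < 2) rr_abort("ICC needs >= 2 regions and >= 2 levels")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0 || (msr == 0 && mse == 0 && msc == 0)) {
    return(structure(NA_real_, flag = "degenerate"))
  }
  (msr - mse) / denom
}

#' Robustness gate
#'
#' @param cv_mean CV_mean in percent (possibly flagged `NA`).
#' @param icc ICC (possibly flagged `NA`).
#' @param cv_threshold,icc_threshold Gate thresholds (defaults 10% and 0.90).
#' @return `TRUE` iff both quantities are defined, `cv_mean < cv_threshold`
#'   and `icc > icc_threshold`; any flag classifies as not robust.
#' @examples
#' classify_robust(5, 0.95)
#' @export
classify_robust <- function(cv_mean, icc, cv_threshold = 10,
                            icc_threshold = 0.90) {
  is.finite(cv_mean) && is.finite(icc) &&
    cv_mean < cv_threshold && icc > icc_threshold
}

# Regions x levels value matrix for one feature x group. Levels are keyed by
# the `level` column when present (the updates group has distinct levels
# with equal numeric x, e.g. 1x32 and 2x16), falling back to x_value;
# columns are ordered by x then label. Returns the matrix and per-level x.
level_matrix <- function(sub) {
  lev <- if ("level" %in% names(sub)) as.character(sub$level)
    else as.character(sub$x_value)
  lv_order <- unique(lev[order(sub$x_value, lev)])
  regs <- sort(unique(sub$region))
  m <- matrix(NA_real_, length(regs), length(lv_order),
              dimnames = list(regs, lv_order))
  idx <- cbind(match(sub$region, regs), match(lev, lv_order))
  if (anyDuplicated(paste(idx[, 1], idx[, 2]))) {
    rr_abort("duplicated region x level records")
  }
  m[idx] <- sub$value
  x <- sub$x_value[match(lv_order, lev)]
  list(m = m, x = x, levels = lv_order)
}

#' Robustness records for a feature table
#'
#' Computes, for every feature x group in a (filtered, aggregated) feature
#' table, the per-region CVs, their mean, the agreement ICC over the
#' complete regions x levels matrix, and the robust flag.
#'
#' @param records Long feature table with columns `feature`, `region`,
#'   `group`, `x_value`, `value`, `valid` (see [extract_features()] /
#'   [simulate_feature_values()]). Invalid records must already have been
#'   handled by [filter_invalid()].
#' @param cv_threshold,icc_threshold Gate thresholds.
#' @return Data frame with one row per feature x group: `feature`, `group`,
#'   `cv_mean`, `icc`, `robust`, `n_regions`, `n_levels`, `flag`.
#' @export
assess_robustness <- function(records, cv_threshold = 10,
                              icc_threshold = 0.90) {
  records <- records[records$valid, , drop = FALSE]
  keys <- unique(records[, c("feature", "group")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- records[records$feature == keys$feature[i] &
                     records$group == keys$group[i], ]
    m <- tryCatch(level_matrix(sub)$m, error = function(e) NULL)
    if (is.null(m) || anyNA(m)) {
      rr_abort(sprintf("feature %s / group %s: incomplete or duplicated regions x levels table",
                       keys$feature[i], keys$group[i]))
    }
    cvs <- apply(m, 1, cv_per_region)
    cvm <- cv_mean(cvs)
    icc <- if (nrow(m) >= 2 && ncol(m) >= 2) icc_agreement(m) else
      structure(NA_real_, flag = "too-few-regions")
    data.frame(
      feature = keys$feature[i], group = keys$group[i],
      cv_mean = as.numeric(cvm), icc = as.numeric(icc),
      robust = classify_robust(as.numeric(cvm), as.numeric(icc),
                               cv_threshold, icc_threshold),
      n_regions = nrow(m), n_levels = ncol(m),
      flag = paste(c(attr(cvm, "flag"), attr(icc, "flag")), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
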