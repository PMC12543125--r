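# Parametric correction of non-robust features. For each feature x group the
# mean across-region response is fitted with the eight candidate forms
# alpha * g(x) + beta by weighted least squares with intrinsic weights
# (reciprocal of the across-region variance at each level), the lowest-AIC
# family wins, and per-region values are corrected with the rearranged form
# (value - beta) / g(x). The algorithm group is categorical and never enters.

#' Fit the eight candidate families by weighted least squares
#'
#' Each family is linear in `(alpha, beta)` given its transform `g(x)`, so
#' the weighted normal equations are solved in closed form. With intrinsic
#' (data-determined, residual-independent) weights, iteratively reweighted
#' least squares converges in this single solve. AIC is the Gaussian
#' weighted-likelihood form `n log(RSS_w / n) + 2k` with `k = 3`
#' (alpha, beta, residual scale); shared constants are dropped. Families
#' whose transform is undefined or infinite at some level (e.g. `log(x)` at
#' `x = 1` in a reciprocal) are inadmissible and carry `AIC = Inf`.
#'
#' @param x Rescaled, strictly positive parameter levels.
#' @param y_mean Mean feature value across regions at each level.
#' @param weights Per-level weights; default the reciprocal of the
#'   across-region variance. Zero-variance levels should be pre-capped via
#'   [intrinsic_weights()].
#' @return Data frame with one row per family: `family`, `alpha`, `beta`,
#'   `rss_w`, `aic`, `n_points`, `admissible`.
#' @examples
#' x <- c(2, 4, 6, 8)
#' fit_candidates(x, 2 / x + 1)
#' @export
fit_candidates <- function(x, y_mean, weights = rep(1, length(x))) {
  if (length(x) < 3) {
    rr_abort("curve fitting needs at least 3 levels",
             class = "radiorobust_unassessable")
  }
  if (length(y_mean) != length(x) || length(weights) != length(x)) {
    rr_abort("x, y_mean and weights must have equal length")
  }
  if (any(x <= 0)) rr_abort("x must be strictly positive after rescaling")
  n <- length(x)
  out <- lapply(model_families(), function(fam) {
    g <- family_transform(fam, x)
    if (any(!is.finite(g))) {
      return(data.frame(family = fam, alpha = NA_real_, beta = NA_real_,
                        rss_w = NA_real_, aic = Inf, n_points = n,
                        admissible = FALSE, stringsAsFactors = FALSE))
    }
    w <- weights
    sw <- sum(w)
    gw <- sum(w * g) / sw
    yw <- sum(w * y_mean) / sw
    sgg <- sum(w * (g - gw)^2)
    alpha <- if (sgg > 0) sum(w * (g - gw) * (y_mean - yw)) / sgg else 0
    beta <- yw - alpha * gw
    rss <- sum(w * (y_mean - alpha * g - beta)^2)
    aic <- n * log(max(rss, .Machine$double.xmin) / n) + 2 * 3
    data.frame(family = fam, alpha = alpha, beta = beta, rss_w = rss,
               aic = aic, n_points = n, admissible = is.finite(aic),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Intrinsic fitting weights from across-region variances
#'
#' Reciprocal of the across-region feature variance at each level, with
#' zero/negligible variances capped at `cap_factor` times the median finite
#' weight so degenerate synthetic inputs cannot produce infinite weights.
#'
#' @param region_values Matrix regions x levels.
#' @param cap_factor Cap multiplier (default `1e6`).
#' @return Per-level weight vector.
#' @export
intrinsic_weights <- function(region_values, cap_factor = 1e6) {
  v <- apply(region_values, 2, stats::var)
  w <- 1 / v
  if (all(!is.finite(w))) {
    return(rep(1, length(w)))
  }
  cap <- cap_factor * stats::median(w[is.finite(w)])
  w[!is.finite(w) | w > cap] <- cap
  w
}

#' Select the best candidate by AIC
#'
#' Minimum-AIC admissible candidate; exact ties resolve to the family listed
#' first in [model_families()] (simplest transform) and are recorded in the
#' `tie` attribute.
#'
#' @param candidates Output of [fit_candidates()].
#' @return Single-row data frame (the winning candidate), or `NULL` with a
#'   message when no candidate is admissible.
#' @export
select_best <- function(candidates) {
  adm <- candidates[candidates$admissible, , drop = FALSE]
  if (nrow(adm) == 0) {
    message("no admissible candidate fit; feature not correctable")
    return(NULL)
  }
  best_i <- which(adm$aic == min(adm$aic))
  out <- adm[best_i[1], , drop = FALSE]
  if (length(best_i) > 1) {
    attr(out, "tie") <- adm$family[best_i]
    message("AIC tie between: ", paste(adm$family[best_i], collapse = ", "),
            "; keeping ", out$family)
  }
  out
}

#' Correct per-region values with the rearranged best-fit function
#'
#' Applies `corrected = (value - beta) / g(x)` with the group-level `beta`
#' of the winning fit, removing the fitted parameter dependence so a feature
#' following `alpha_r * g(x) + beta` exactly becomes the constant `alpha_r`.
#'
#' @param values Matrix regions x levels of raw feature values.
#' @param best Winning candidate from [select_best()].
#' @param x Rescaled levels (columns of `values`).
#' @return Matrix of corrected values, same shape as `values`.
#' @export
apply_correction <- function(values, best, x) {
  g <- family_transform(best$family, x)
  if (any(!is.finite(g)) || any(g == 0)) {
    rr_abort("correction transform is zero or undefined at some level; check rescale_x()")
  }
  sweep(sweep(values, 2, rep(best$beta, length(x)), "-"), 2, g, "/")
}

#' Classify correctability of one feature x group
#'
#' Compares per-region CVs before and after correction with a one-sided
#' Wilcoxon signed-rank test (post < pre; exact distribution for small
#' samples without ties) and requires an ICC point improvement. A feature is
#' `correctable` when the reduction is significant, ICC improved and the
#' corrected values meet the robust gate; `moderately correctable` when the
#' significant improvement falls short of the gate; `not correctable`
#' otherwise.
#'
#' @param cv_pre,cv_post Paired per-region CVs (same regions, same order).
#' @param icc_pre,icc_post ICC before/after correction.
#' @param cv_mean_post Mean corrected CV (computed from `cv_post` when
#'   omitted).
#' @param alpha Significance level (default 0.05).
#' @param cv_threshold,icc_threshold Robust-gate thresholds.
#' @return List with `category`, `wilcoxon_p`, `cv_mean_post`, `icc_post`.
#' @export
classify_correctability <- function(cv_pre, cv_post, icc_pre, icc_post,
                                    cv_mean_post = NULL, alpha = 0.05,
                                    cv_threshold = 10, icc_threshold = 0.90) {
  keep <- is.finite(cv_pre) & is.finite(cv_post)
  cv_pre <- cv_pre[keep]
  cv_post <- cv_post[keep]
  if (length(cv_pre) < 2) {
    return(list(category = "not correctable", wilcoxon_p = NA_real_,
                cv_mean_post = if (is.null(cv_mean_post)) NA_real_ else cv_mean_post,
                icc_post = icc_post, note = "fewer than 2 paired regions"))
  }
  if (is.null(cv_mean_post)) cv_mean_post <- mean(cv_post)
  p <- if (all(cv_post == cv_pre)) {
    1  # no change anywhere: no evidence of reduction
  } else {
    suppressWarnings(stats::wilcox.test(cv_pre, cv_post, paired = TRUE,
                                        alternative = "greater")$p.value)
  }
  improved <- is.finite(icc_pre) && is.finite(icc_post) && icc_post > icc_pre
  category <- if (is.finite(p) && p < alpha && improved) {
    if (cv_mean_post < cv_threshold && is.finite(icc_post) &&
        icc_post > icc_threshold) "correctable" else "moderately correctable"
  } else {
    "not correctable"
  }
  list(category = category, wilcoxon_p = p, cv_mean_post = cv_mean_post,
       icc_post = icc_post)
}

#' Run the correction stage over a feature table
#'
#' For every non-robust feature x group in `robustness` (the categorical
#' algorithm group excluded), fits the candidate families to the mean
#' response with intrinsic weights, selects by AIC, corrects per-region
#' values and classifies correctability.
#'
#' @param records Filtered/aggregated long feature table.
#' @param robustness Output of [assess_robustness()].
#' @param alpha Significance level for the Wilcoxon gate.
#' @param cv_threshold,icc_threshold Robust-gate thresholds.
#' @return List with `outcomes` (one row per processed feature x group:
#'   winning family, coefficients, Wilcoxon p, pre/post CV_mean and ICC,
#'   category) and `fits` (all eight candidates per feature x group).
#' @export
correct_features <- function(records, robustness, alpha = 0.05,
                             cv_threshold = 10, icc_threshold = 0.90) {
  todo <- robustness[!robustness$robust & robustness$group != "algorithm", ,
                     drop = FALSE]
  outcomes <- list()
  fits <- list()
  for (i in seq_len(nrow(todo))) {
    feat <- todo$feature[i]
    grp <- todo$group[i]
    sub <- records[records$feature == feat & records$group == grp &
                     records$valid, ]
    lm_ <- level_matrix(sub)
    m <- lm_$m
    xs <- lm_$x
    xr <- rescale_x(grp, xs)
    if (length(unique(xs)) < 3) {
      outcomes[[length(outcomes) + 1]] <- data.frame(
        feature = feat, group = grp, family = NA_character_,
        alpha = NA_real_, beta = NA_real_, wilcoxon_p = NA_real_,
        cv_mean_pre = todo$cv_mean[i], icc_pre = todo$icc[i],
        cv_mean_post = NA_real_, icc_post = NA_real_,
        category = "unassessable", stringsAsFactors = FALSE)
      next
    }
    w <- intrinsic_weights(m)
    y_mean <- colMeans(m)
    cand <- fit_candidates(xr, y_mean, w)
    cand$feature <- feat
    cand$group <- grp
    fits[[length(fits) + 1]] <- cand
    best <- select_best(cand)
    if (is.null(best)) {
      outcomes[[length(outcomes) + 1]] <- data.frame(
        feature = feat, group = grp, family = NA_character_,
        alpha = NA_real_, beta = NA_real_, wilcoxon_p = NA_real_,
        cv_mean_pre = todo$cv_mean[i], icc_pre = todo$icc[i],
        cv_mean_post = NA_real_, icc_post = NA_real_,
        category = "not correctable", stringsAsFactors = FALSE)
      next
    }
    corrected <- apply_correction(m, best, xr)
    cv_pre <- apply(m, 1, cv_per_region)
    cv_post <- apply(corrected, 1, cv_per_region)
    icc_post <- tryCatch(as.numeric(icc_agreement(corrected)),
                         error = function(e) NA_real_)
    cls <- classify_correctability(
      cv_pre, cv_post, icc_pre = todo$icc[i], icc_post = icc_post,
      cv_mean_post = as.numeric(cv_mean(cv_post)), alpha = alpha,
      cv_threshold = cv_threshold, icc_threshold = icc_threshold)
    outcomes[[length(outcomes) + 1]] <- data.frame(
      feature = feat, group = grp, family = best$family,
      alpha = best$alpha, beta = best$beta, wilcoxon_p = cls$wilcoxon_p,
      cv_mean_pre = todo$cv_mean[i], icc_pre = todo$icc[i],
      cv_mean_post = cls$cv_mean_post, icc_post = icc_post,
      category = cls$category, stringsAsFactors = FALSE)
  }
  list(
    outcomes = if (length(outcomes)) do.call(rbind, outcomes) else NULL,
    fits = if (length(fits)) do.call(rbind, fits) else NULL
  )
}
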