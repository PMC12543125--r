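# Study-level summaries: predicted probabilities of robust / correctable
# outcomes from logistic mixed models with feature-specific random
# intercepts, pairwise group comparisons with a two-sample Cramér-von Mises
# permutation test under Bonferroni adjustment, and odds ratios contrasting
# volume/intensity effects against the varied parameter.

#' Predicted-probability summary per level of a categorical predictor
#'
#' Fits `outcome ~ X + (1 | feature)` by logistic mixed-effects regression
#' and computes each feature's predicted probability
#' `PP = 1 / (1 + exp(-(b + a X + u_feature)))` including its random
#' intercept, then summarises the per-feature PPs of each level of `X` as
#' median and interquartile range. Levels whose outcomes are all 0 or all 1
#' are flagged as degenerate (complete separation pushes their PP to the
#' boundary).
#'
#' @param outcomes Data frame with columns `feature`, `x` (categorical
#'   predictor: family or investigation group) and `outcome` (0/1).
#' @return List with `summary` (per level: `x`, `median_pp`, `q25`, `q75`,
#'   `n_features`, `degenerate`) and `pp` (per feature x level predicted
#'   probabilities).
#' @export
pp_summary <- function(outcomes) {
  stopifnot(all(c("feature", "x", "outcome") %in% names(outcomes)))
  if (!all(outcomes$outcome %in% c(0, 1))) {
    rr_abort("outcomes must be 0/1")
  }
  d <- data.frame(feature = factor(outcomes$feature),
                  x = factor(outcomes$x),
                  outcome = outcomes$outcome)
  form <- if (nlevels(d$x) >= 2) outcome ~ x + (1 | feature)
    else outcome ~ 1 + (1 | feature)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(form, data = d, family = stats::binomial,
                  control = lme4::glmerControl(check.conv.singular = "ignore"))
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    # fall back to the fixed-effects logistic fit (random variance ~ 0)
    form0 <- if (nlevels(d$x) >= 2) outcome ~ x else outcome ~ 1
    fit0 <- stats::glm(form0, data = d, family = stats::binomial)
    d$pp <- stats::plogis(stats::predict(fit0, type = "link"))
  } else {
    d$pp <- stats::predict(fit, type = "response")
  }
  agg <- lapply(split(d, d$x), function(s) {
    q <- stats::quantile(s$pp, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(x = as.character(s$x[1]), median_pp = q[2], q25 = q[1],
               q75 = q[3], n_features = length(unique(s$feature)),
               degenerate = length(unique(s$outcome)) == 1,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, agg)
  rownames(summary) <- NULL
  list(summary = summary,
       pp = d[, c("feature", "x", "outcome", "pp")])
}

# Two-sample Cramér-von Mises statistic on the pooled empirical CDFs:
# T = nm/(n+m)^2 * sum over pooled points of (F_n - G_m)^2. Rank-based, so
# invariant under strictly monotone transforms; ties are handled through the
# pooled-point evaluation.
cvm_statistic <- function(a, b) {
  n <- length(a)
  m <- length(b)
  pooled <- sort(c(a, b))
  fa <- vapply(pooled, function(t) sum(a <= t), numeric(1)) / n
  fb <- vapply(pooled, function(t) sum(b <= t), numeric(1)) / m
  n * m / (n + m)^2 * sum((fa - fb)^2)
}

#' Two-sample Cramér-von Mises permutation test
#'
#' Computes the two-sample CvM statistic and a permutation p-value: full
#' enumeration of the `choose(n+m, n)` group assignments when that count is
#' at most `enum_limit`, otherwise `n_perm` seeded Monte-Carlo permutations
#' with the `(b + 1) / (n_perm + 1)` estimator.
#'
#' @param a,b Numeric samples (e.g. per-feature predicted probabilities of
#'   two investigation groups).
#' @param n_perm Monte-Carlo permutation count (default 9999, resolving
#'   p-values well below 0.05/36).
#' @param seed Seed for the Monte-Carlo branch.
#' @param enum_limit Maximum number of splits enumerated exactly.
#' @return List with `statistic`, `p`, and `method` ("enumeration" or
#'   "permutation").
#' @examples
#' cvm_two_sample(c(1, 2), c(3, 4))$p
#' @export
cvm_two_sample <- function(a, b, n_perm = 9999, seed = 1,
                           enum_limit = 1e5) {
  if (length(a) == 0 || length(b) == 0) rr_abort("empty sample")
  n <- length(a)
  m <- length(b)
  N <- n + m
  pooled <- c(a, b)
  ord <- order(pooled)
  ps <- pooled[ord]
  # tied values form blocks; the empirical CDFs step at the end of a block
  # and each pooled point of the block contributes the block-end difference
  last <- which(c(ps[-1] != ps[-N], TRUE))
  size <- diff(c(0, last))
  stat_fn <- function(in_a_sorted) {
    d <- cumsum(in_a_sorted) / n - cumsum(!in_a_sorted) / m
    n * m / N^2 * sum(size * d[last]^2)
  }
  actual <- logical(N)
  actual[seq_len(n)] <- TRUE
  obs <- stat_fn(actual[ord])
  n_splits <- choose(N, n)
  eps <- 1e-12
  if (n_splits <= enum_limit) {
    combs <- utils::combn(N, n)
    cnt <- 0L
    for (i in seq_len(ncol(combs))) {
      in_a <- logical(N)
      in_a[combs[, i]] <- TRUE
      if (stat_fn(in_a) >= obs - eps) cnt <- cnt + 1L
    }
    list(statistic = obs, p = cnt / ncol(combs), method = "enumeration")
  } else {
    cnt <- with_rr_seed(seed, {
      hits <- 0L
      for (i in seq_len(n_perm)) {
        in_a <- logical(N)
        in_a[sample.int(N, n)] <- TRUE
        if (stat_fn(in_a) >= obs - eps) hits <- hits + 1L
      }
      hits
    })
    list(statistic = obs, p = (cnt + 1) / (n_perm + 1),
         method = "permutation")
  }
}

#' Bonferroni adjustment with an explicit comparison count
#'
#' @param p Raw p-values.
#' @param m Number of comparisons (defaults to `length(p)`; 36 for all
#'   pairs of 9 groups).
#' @return `pmin(1, p * m)`.
#' @examples
#' bonferroni(0.001, 36)
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) rr_abort("m must be at least the number of tests")
  pmin(1, p * m)
}

#' All pairwise group comparisons of per-feature predicted probabilities
#'
#' @param pp Per-feature PP table from [pp_summary()] (`x` = group).
#' @param n_perm,seed Passed to [cvm_two_sample()].
#' @return Data frame: `group_a`, `group_b`, `statistic`, `p_raw`,
#'   `p_adjusted` (Bonferroni over all pairs).
#' @export
pairwise_group_tests <- function(pp, n_perm = 9999, seed = 1) {
  groups <- sort(unique(as.character(pp$x)))
  pairs <- utils::combn(groups, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pp$pp[pp$x == pairs[1, i]]
    b <- pp$pp[pp$x == pairs[2, i]]
    tst <- cvm_two_sample(a, b, n_perm = n_perm,
                          seed = derive_seed(seed, paste(pairs[, i], collapse = "-")))
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               statistic = tst$statistic, p_raw = tst$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bonferroni(out$p_raw, m = ncol(pairs))
  out
}

#' Odds ratios for volume/intensity effects relative to the parameter
#'
#' From the per-feature significance indicators of the attribution stage,
#' fits `significant ~ effect_type + (1 | feature)` by logistic
#' mixed-effects regression within a group and reports the volume-vs-
#' parameter and intensity-vs-parameter contrasts as odds ratios with Wald
#' 95% confidence intervals. Complete separation (an effect type uniformly
#' significant or not) is flagged and its CI reported as unbounded.
#'
#' @param effects Output of [assess_effects()] for one group.
#' @return Data frame: `group`, `contrast`, `or`, `ci_low`, `ci_high`,
#'   `significant`, `separation`.
#' @export
effect_odds_ratios <- function(effects) {
  eff <- effects[effects$converged %in% TRUE, , drop = FALSE]
  if (nrow(eff) < 2) rr_abort("need >= 2 converged features")
  long <- data.frame(
    feature = rep(eff$feature, 3),
    effect_type = factor(rep(c("parameter", "volume", "intensity"),
                             each = nrow(eff)),
                         levels = c("parameter", "volume", "intensity")),
    sig = as.integer(c(eff$sig_parameter, eff$sig_volume, eff$sig_intensity))
  )
  rates <- tapply(long$sig, long$effect_type, mean)
  sep <- stats::setNames(rates %in% c(0, 1), names(rates))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::glmer(sig ~ effect_type + (1 | feature), data = long,
                  family = stats::binomial,
                  control = lme4::glmerControl(check.conv.singular = "ignore"))
    )),
    error = function(e) NULL
  )
  mk <- function(term, contrast, sep_flag) {
    if (is.null(fit) || sep_flag) {
      return(data.frame(group = eff$group[1], contrast = contrast,
                        or = NA_real_, ci_low = NA_real_, ci_high = Inf,
                        significant = NA, separation = TRUE,
                        stringsAsFactors = FALSE))
    }
    cf <- suppressWarnings(stats::coef(summary(fit)))
    est <- cf[term, "Estimate"]
    se <- cf[term, "Std. Error"]
    ci <- exp(est + c(-1, 1) * stats::qnorm(0.975) * se)
    data.frame(group = eff$group[1], contrast = contrast, or = exp(est),
               ci_low = ci[1], ci_high = ci[2],
               significant = ci[1] > 1 || ci[2] < 1, separation = FALSE,
               stringsAsFactors = FALSE)
  }
  rbind(
    mk("effect_typevolume", "volume vs parameter", sep["parameter"] || sep["volume"]),
    mk("effect_typeintensity", "intensity vs parameter", sep["parameter"] || sep["intensity"])
  )
}
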