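# Curve fitting, AIC selection, rearranged-function correction, and the
# correctability gate.

test_that("exact model-class data are recovered to numerical precision", {
  x <- c(2, 5, 10, 20, 40)
  cand <- fit_candidates(x, 2 / x + 1)
  hit <- cand[cand$family == "a/x+b", ]
  expect_equal(hit$alpha, 2, tolerance = 1e-10)
  expect_equal(hit$beta, 1, tolerance = 1e-10)
  expect_equal(select_best(cand)$family, "a/x+b")
  # every family recovers its own exact data
  for (fam in model_families()) {
    y <- 0.7 * family_transform(fam, x) - 2
    f <- fit_candidates(x, y)
    row <- f[f$family == fam, ]
    expect_equal(row$alpha, 0.7, tolerance = 1e-8)
    expect_equal(row$beta, -2, tolerance = 1e-8)
    expect_equal(select_best(f)$family, fam)
  }
})

test_that("constant response degenerates to zero slope and the weighted mean", {
  x <- c(2, 4, 8, 16)
  w <- c(1, 2, 3, 4)
  cand <- fit_candidates(x, rep(3.5, 4), weights = w)
  expect_true(all(abs(cand$alpha) < 1e-10))
  expect_true(all(abs(cand$beta - 3.5) < 1e-10))
  # all AICs equal: tie resolves to the first family and is reported
  expect_message(best <- select_best(cand), "tie")
  expect_equal(best$family, model_families()[1])
})

test_that("weighted fits match a dense grid-search minimiser", {
  set.seed(11)
  x <- rescale_x("acquisition_time", c(1, 2, 4, 8, 15))
  w <- runif(5, 0.5, 2)
  for (fam in c("a*x+b", "a/x+b", "a*log(x)+b")) {
    y <- 1.3 * family_transform(fam, x) + 0.8 + rnorm(5, sd = 0.3)
    fit <- fit_candidates(x, y, w)
    fit <- fit[fit$family == fam, ]
    g <- family_transform(fam, x)
    oracle <- oracle_wls_grid(g, y, w, fit$alpha + c(-0.2, 0.2),
                              fit$beta + c(-0.2, 0.2))
    expect_equal(fit$alpha, oracle$alpha, tolerance = 2e-3)
    expect_equal(fit$beta, oracle$beta, tolerance = 2e-3)
    expect_lte(fit$rss_w, oracle$rss + 1e-8)
  }
})

test_that("fitting preconditions are enforced", {
  expect_error(fit_candidates(c(1, 2), c(1, 2)), "3 levels")
  expect_error(fit_candidates(c(-1, 2, 3), c(1, 2, 3)), "positive")
  # reciprocal-log family inadmissible at x = 1 (log 0 division)
  cand <- fit_candidates(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_false(cand$admissible[cand$family == "a/log(x)+b"])
  expect_true(all(cand$admissible[cand$family != "a/log(x)+b"]))
  none <- cand
  none$admissible <- FALSE
  none$aic <- Inf
  expect_message(expect_null(select_best(none)), "not correctable")
})

test_that("zero-variance levels get capped, finite weights", {
  m <- rbind(c(1, 2, 3), c(1, 2.1, 3.3))
  m[, 1] <- 5  # zero across-region variance at level 1
  w <- intrinsic_weights(m)
  expect_true(all(is.finite(w)))
  expect_equal(w[1], max(w))
})

test_that("rearranged correction flattens exact data and the identity limit holds", {
  x <- rescale_x("gaussian_fwhm", seq(0, 10, 2))
  g <- family_transform("a*log(x)+b", x)
  alpha_r <- c(2, 3, 4)
  vals <- outer(alpha_r, g) + 1.5
  best <- data.frame(family = "a*log(x)+b", alpha = 3, beta = 1.5)
  corr <- apply_correction(vals, best, x)
  expect_equal(corr, matrix(alpha_r, 3, length(x)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(corr, 1, cv_per_region), rep(0, 3))
  # beta misspecified: correction cannot flatten
  best_bad <- transform(best, beta = 1.0)
  corr_bad <- apply_correction(vals, best_bad, x)
  expect_true(all(apply(corr_bad, 1, cv_per_region) > 0))
  # alpha = 0 family with beta = value: corrected values all zero slope
  const <- matrix(4, 3, length(x))
  corr0 <- apply_correction(const, data.frame(family = "a*x+b", alpha = 0,
                                              beta = 4), x)
  expect_equal(corr0, matrix(0, 3, length(x)), ignore_attr = TRUE)
})

test_that("Wilcoxon gate matches full sign-assignment enumeration", {
  set.seed(5)
  pre <- runif(9, 10, 30)
  post <- pre - runif(9, -2, 8)
  cls <- classify_correctability(pre, post, icc_pre = 0.5, icc_post = 0.9)
  expect_equal(cls$wilcoxon_p, oracle_wilcoxon_exact(pre, post),
               tolerance = 1e-12)
  # maximal improvement is correctable
  out <- classify_correctability(rep(20, 9), rep(0, 9), 0.5, 1)
  expect_equal(out$category, "correctable")
  # no change: p = 1, not correctable
  same <- classify_correctability(pre, pre, 0.5, 0.9)
  expect_equal(same$wilcoxon_p, 1)
  expect_equal(same$category, "not correctable")
  # significant reduction but gate unmet: moderately correctable
  mid <- classify_correctability(rep(60, 9), rep(30, 9) + rnorm(9, sd = 0.1),
                                 0.2, 0.5)
  expect_equal(mid$category, "moderately correctable")
  # too few pairs
  expect_equal(classify_correctability(c(1, NA), c(0, NA), 0, 1)$category,
               "not correctable")
})

test_that("AIC recovers the generative family on low-noise synthetic tables", {
  hits <- 0
  total <- 0
  x_raw <- c(1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12.5, 15)
  for (fam in c("a*x+b", "a/x^2+b", "a*log(x)+b", "a/log(x)+b")) {
    # noise at 2% of the family's own response range
    sigma <- 0.02 * diff(range(family_transform(
      fam, rescale_x("acquisition_time", x_raw))))
    for (seed in 1:10) {
      tab <- simulate_feature_values(fam, "acquisition_time", x = x_raw,
                                     sigma = sigma, seed = seed)
      xs <- sort(unique(tab$x_value))
      m <- do.call(rbind, lapply(split(tab, tab$region), function(s) {
        s$value[order(s$x_value)]
      }))
      cand <- fit_candidates(rescale_x("acquisition_time", xs), colMeans(m),
                             intrinsic_weights(m))
      total <- total + 1
      if (select_best(cand)$family == fam) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("correction stage runs end to end on simulated non-robust features", {
  tab <- simulate_feature_values("a/x+b", "bpl_beta",
                                 x = c(50, 100, 200, 400, 800),
                                 n_regions = 6, alpha_range = c(400, 500),
                                 beta_range = c(1, 1), sigma = 0, seed = 8)
  rr <- assess_robustness(tab)
  expect_false(rr$robust)
  out <- correct_features(tab, rr)
  expect_equal(out$outcomes$family, "a/x+b")
  expect_equal(out$outcomes$category, "correctable")
  expect_lt(out$outcomes$cv_mean_post, 1e-6)
  expect_equal(nrow(out$fits), 8)
  # the categorical algorithm group is never processed
  tab$group <- "algorithm"
  rr2 <- assess_robustness(tab)
  out2 <- correct_features(tab, rr2)
  expect_null(out2$outcomes)
})
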