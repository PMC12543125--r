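# Predicted-probability summaries, Cramér-von Mises permutation testing,
# Bonferroni arithmetic, and odds-ratio contrasts.

test_that("predicted probabilities honour the logistic closed form", {
  # b = 0, a = 0, no random intercept: PP = 1/(1 + exp(0)) = 0.5
  expect_equal(stats::plogis(0), 0.5)
  # outcomes independent of x with a 50% rate: PP medians near 0.5 everywhere
  set.seed(4)
  d <- expand.grid(feature = paste0("f", 1:40), x = c("g1", "g2", "g3"),
                   stringsAsFactors = FALSE)
  d$outcome <- rbinom(nrow(d), 1, 0.5)
  pp <- pp_summary(d)
  expect_true(all(abs(pp$summary$median_pp - 0.5) < 0.25))
  expect_equal(nrow(pp$summary), 3)
  expect_true(all(pp$pp$pp > 0 & pp$pp$pp < 1))
  # median within IQR
  expect_true(all(pp$summary$q25 <= pp$summary$median_pp &
                    pp$summary$median_pp <= pp$summary$q75))
})

test_that("an all-negative group is summarised as degenerate near-zero PP", {
  set.seed(9)
  d <- expand.grid(feature = paste0("f", 1:30), x = c("stable", "fragile"),
                   stringsAsFactors = FALSE)
  d$outcome <- ifelse(d$x == "fragile", 0L, rbinom(nrow(d) / 2, 1, 0.6))
  pp <- pp_summary(d)
  frag <- pp$summary[pp$summary$x == "fragile", ]
  expect_lt(frag$median_pp, 0.05)
  expect_true(frag$degenerate)
})

test_that("PP medians are invariant to feature relabeling", {
  set.seed(12)
  d <- expand.grid(feature = paste0("f", 1:25), x = c("a", "b"),
                   stringsAsFactors = FALSE)
  d$outcome <- rbinom(nrow(d), 1, ifelse(d$x == "a", 0.3, 0.7))
  p1 <- pp_summary(d)$summary
  perm <- sample(unique(d$feature))
  d2 <- d
  d2$feature <- perm[match(d$feature, unique(d$feature))]
  p2 <- pp_summary(d2)$summary
  expect_equal(p1$median_pp, p2$median_pp, tolerance = 1e-6)
})

test_that("CvM statistic and enumeration p match the independent oracle", {
  a <- c(1, 2)
  b <- c(3, 4)
  res <- cvm_two_sample(a, b)
  expect_equal(res$method, "enumeration")
  expect_equal(res$statistic, oracle_cvm_stat(a, b), tolerance = 1e-12)
  expect_equal(res$p, oracle_cvm_p(a, b), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:5) {
    a <- round(rnorm(sample(3:6, 1)), 2)
    b <- round(rnorm(sample(3:6, 1)), 2)
    res <- cvm_two_sample(a, b)
    expect_equal(res$statistic, oracle_cvm_stat(a, b), tolerance = 1e-12)
    expect_equal(res$p, oracle_cvm_p(a, b), tolerance = 1e-12)
  }
  # identical multisets: minimal statistic, p = 1
  res_id <- cvm_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res_id$p, 1)
  expect_error(cvm_two_sample(numeric(0), 1), "empty")
})

test_that("CvM statistic is invariant under strictly monotone transforms", {
  set.seed(31)
  a <- runif(8)
  b <- runif(7)
  s1 <- cvm_two_sample(a, b, n_perm = 99, seed = 1)$statistic
  s2 <- cvm_two_sample(exp(5 * a), exp(5 * b), n_perm = 99, seed = 1)$statistic
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("Monte-Carlo branch is seeded and uses the +1 correction", {
  set.seed(2)
  a <- rnorm(12)
  b <- rnorm(12)
  r1 <- cvm_two_sample(a, b, n_perm = 199, seed = 7)
  r2 <- cvm_two_sample(a, b, n_perm = 199, seed = 7)
  expect_equal(r1$method, "permutation")
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 200)
})

test_that("Bonferroni arithmetic is capped multiplication", {
  expect_equal(bonferroni(0.001, 36), 0.036)
  expect_equal(bonferroni(0.5, 36), 1)
  expect_equal(bonferroni(c(0.2, 0.04)), c(0.4, 0.08))
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_error(bonferroni(c(0.1, 0.2), 1), "at least")
  # never decreases
  p <- runif(10)
  expect_true(all(bonferroni(p, 12) >= p))
})

test_that("pairwise group tests adjust over all pairs", {
  set.seed(14)
  pp <- expand.grid(feature = paste0("f", 1:15), x = c("a", "b", "c"),
                    stringsAsFactors = FALSE)
  pp$pp <- runif(nrow(pp))
  res <- pairwise_group_tests(pp, n_perm = 99, seed = 3)
  expect_equal(nrow(res), 3)
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 3))
})

test_that("odds ratios recover planted significance-rate contrasts", {
  set.seed(8)
  n <- 120
  eff <- data.frame(
    feature = paste0("f", 1:n), group = "gaussian_fwhm",
    sig_parameter = rbinom(n, 1, 0.2) == 1,
    sig_volume = rbinom(n, 1, 0.6) == 1,
    sig_intensity = rbinom(n, 1, 0.2) == 1,
    converged = TRUE
  )
  or <- effect_odds_ratios(eff)
  vol <- or[or$contrast == "volume vs parameter", ]
  expect_gt(vol$or, 1)
  expect_true(vol$ci_low > 1)  # 0.6 vs 0.2 with n = 120 separates cleanly
  expect_true(vol$ci_low < vol$or & vol$or < vol$ci_high)
  int <- or[or$contrast == "intensity vs parameter", ]
  expect_false(isTRUE(int$significant))
  # identical patterns: OR 1, CI spans 1
  eff$sig_volume <- eff$sig_parameter
  eff$sig_intensity <- eff$sig_parameter
  or2 <- effect_odds_ratios(eff)
  expect_equal(or2$or[1], 1, tolerance = 1e-6)
  expect_true(or2$ci_low[1] < 1 & or2$ci_high[1] > 1)
  # uniform significance: separation flagged
  eff$sig_volume <- TRUE
  or3 <- effect_odds_ratios(eff)
  expect_true(or3$separation[or3$contrast == "volume vs parameter"])
})
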