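# Independent oracles used to cross-check the package's own computations.
# These deliberately use different routes (aov decompositions, brute-force
# enumeration, dense grid search) than the implementation.

# Two-way ANOVA mean squares via stats::aov on the long layout.
oracle_icc <- function(m) {
  long <- data.frame(
    value = as.vector(m),
    region = factor(rep(seq_len(nrow(m)), ncol(m))),
    level = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  tab <- summary(stats::aov(value ~ region + level, data = long))[[1]]
  msr <- tab["region", "Mean Sq"]
  msc <- tab["level", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m)
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Dense 2D grid search minimising the weighted RSS of alpha*g(x)+beta.
oracle_wls_grid <- function(g, y, w, alpha_range, beta_range, n_grid = 401) {
  alphas <- seq(alpha_range[1], alpha_range[2], length.out = n_grid)
  betas <- seq(beta_range[1], beta_range[2], length.out = n_grid)
  best <- c(NA, NA, Inf)
  for (a in alphas) {
    rss <- vapply(betas, function(b) sum(w * (y - a * g - b)^2), numeric(1))
    i <- which.min(rss)
    if (rss[i] < best[3]) best <- c(a, betas[i], rss[i])
  }
  list(alpha = best[1], beta = best[2], rss = best[3])
}

# Exact one-sided Wilcoxon signed-rank p (greater: pre > post) by full
# enumeration of all sign assignments, no ties/zeros assumed.
oracle_wilcoxon_exact <- function(pre, post) {
  d <- pre - post
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mean(w_all >= w_obs)
}

# Independent two-sample CvM statistic from ecdf objects.
oracle_cvm_stat <- function(a, b) {
  fa <- stats::ecdf(a)
  fb <- stats::ecdf(b)
  pooled <- c(a, b)
  length(a) * length(b) / length(pooled)^2 *
    sum((fa(pooled) - fb(pooled))^2)
}

# Full-split enumeration p-value for the two-sample CvM test.
oracle_cvm_p <- function(a, b) {
  n <- length(a)
  pooled <- c(a, b)
  obs <- oracle_cvm_stat(a, b)
  combs <- utils::combn(length(pooled), n)
  stats_all <- apply(combs, 2, function(ix) {
    oracle_cvm_stat(pooled[ix], pooled[-ix])
  })
  mean(stats_all >= obs - 1e-12)
}

# Brute-force GLCM counts: loop over every voxel and every 26-neighbour
# offset pair (both directions), counting co-occurrences inside the VOI.
oracle_glcm <- function(arr, n_levels) {
  d <- dim(arr)
  P <- matrix(0, n_levels, n_levels)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    v1 <- arr[x, y, z]
    if (is.na(v1)) next
    for (o in seq_len(nrow(offs))) {
      p <- c(x, y, z) + offs[o, ]
      if (any(p < 1) || any(p > d)) next
      v2 <- arr[p[1], p[2], p[3]]
      if (is.na(v2)) next
      P[v1, v2] <- P[v1, v2] + 1
    }
  }
  P
}

# Brute-force dependence counts (GLDM, alpha = 0).
oracle_gldm <- function(arr, n_levels) {
  d <- dim(arr)
  res <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  dep <- c()
  g <- c()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    v1 <- arr[x, y, z]
    if (is.na(v1)) next
    cnt <- 0
    for (o in seq_len(nrow(offs))) {
      p <- c(x, y, z) + offs[o, ]
      if (any(p < 1) || any(p > d)) next
      v2 <- arr[p[1], p[2], p[3]]
      if (!is.na(v2) && v2 == v1) cnt <- cnt + 1
    }
    dep <- c(dep, cnt + 1)
    g <- c(g, v1)
  }
  P <- matrix(0, n_levels, max(dep))
  for (i in seq_along(dep)) P[g[i], dep[i]] <- P[g[i], dep[i]] + 1
  P
}

# Random VOI-like array with NAs outside an ellipsoid-ish region.
random_voi_array <- function(dims, n_levels, seed, na_frac = 0.3) {
  set.seed(seed)
  arr <- array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
  arr[stats::runif(prod(dims)) < na_frac] <- NA_integer_
  arr
}
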