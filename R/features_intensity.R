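# First-order and texture feature computations. Definitions follow the IBSI
# reference formulations as realised in the common 107-feature set; all
# logarithms in entropy-type features are base 2 with 0 log 0 = 0.

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

firstorder_features <- function(values, binned, voxel_volume) {
  n <- length(values)
  p <- tabulate(binned) / n
  p <- p[p > 0]
  m <- mean(values)
  v <- mean((values - m)^2)   # population variance
  q <- stats::quantile(values, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE)
  inr <- values[values >= q[1] & values <= q[5]]
  c(
    Energy = sum(values^2),
    TotalEnergy = voxel_volume * sum(values^2),
    Entropy = -sum(xlog2(p)),
    Minimum = min(values),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(values),
    Mean = m,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - m)),
    RobustMeanAbsoluteDeviation =
      if (length(inr)) mean(abs(inr - mean(inr))) else 0,
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = if (v > 0) mean((values - m)^3) / v^1.5 else 0,
    Kurtosis = if (v > 0) mean((values - m)^4) / v^2 else 0,
    Variance = v,
    Uniformity = sum(p^2)
  )
}

glcm_features <- function(P) {
  tot <- sum(P)
  if (tot == 0) return(NULL)
  p <- P / tot
  lev <- seq_len(nrow(p))
  ng <- nrow(p)
  px <- rowSums(p)
  py <- colSums(p)  # equal to px for the symmetric matrix
  mu_x <- sum(lev * px)
  mu_y <- sum(lev * py)
  sd_x <- sqrt(sum(px * (lev - mu_x)^2))
  sd_y <- sqrt(sum(py * (lev - mu_y)^2))
  I <- matrix(lev, ng, ng)
  J <- t(I)
  dif <- abs(I - J)
  smm <- I + J
  p_diff <- vapply(0:(ng - 1), function(k) sum(p[dif == k]), numeric(1))
  p_sum <- vapply(2:(2 * ng), function(k) sum(p[smm == k]), numeric(1))
  da <- sum((0:(ng - 1)) * p_diff)
  hx <- -sum(xlog2(px))
  hy <- -sum(xlog2(py))
  hxy <- -sum(xlog2(p))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hxy2 <- -sum(xlog2(pxpy))
  corr <- if (sd_x > 0 && sd_y > 0) {
    (sum(I * J * p) - mu_x * mu_y) / (sd_x * sd_y)
  } else 1
  mcc <- if (ng > 1 && all(px > 0)) {
    Q <- matrix(0, ng, ng)
    for (k in seq_len(ng)) {
      if (py[k] > 0) Q <- Q + outer(p[, k], p[, k]) / (px * py[k])
    }
    evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(evq[min(2, length(evq))], 0))
  } else 1
  c(
    Autocorrelation = sum(I * J * p),
    JointAverage = mu_x,
    ClusterProminence = sum((I + J - mu_x - mu_y)^4 * p),
    ClusterShade = sum((I + J - mu_x - mu_y)^3 * p),
    ClusterTendency = sum((I + J - mu_x - mu_y)^2 * p),
    Contrast = sum((I - J)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(xlog2(p_diff)),
    DifferenceVariance = sum(((0:(ng - 1)) - da)^2 * p_diff),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0)),
    Idm = sum(p / (1 + (I - J)^2)),
    Idmn = sum(p / (1 + ((I - J) / ng)^2)),
    Id = sum(p / (1 + dif)),
    Idn = sum(p / (1 + dif / ng)),
    InverseVariance = sum(p[dif > 0] / dif[dif > 0]^2),
    MaximumProbability = max(p),
    SumAverage = sum((2:(2 * ng)) * p_sum),
    SumEntropy = -sum(xlog2(p_sum)),
    SumSquares = sum((I - mu_x)^2 * p),
    MCC = mcc
  )
}

# Shared skeleton for the run-length / size-zone style families: P is a
# levels x sizes matrix of counts, n_vox the voxel count, n_obs a
# normaliser for the "percentage" feature (voxels per observation chance).
rl_style_features <- function(P, n_vox, n_obs, prefix) {
  nr <- sum(P)
  if (nr == 0) return(NULL)
  p <- P / nr
  i <- seq_len(nrow(P))
  j <- seq_len(ncol(P))
  pg <- rowSums(P)
  ps <- colSums(P)
  i2 <- matrix(i^2, nrow(P), ncol(P))
  j2 <- matrix(j^2, nrow(P), ncol(P), byrow = TRUE)
  mu_i <- sum(rowSums(p) * i)
  mu_j <- sum(colSums(p) * j)
  vals <- c(
    sum(P / j2) / nr,                     # small/short emphasis
    sum(P * j2) / nr,                     # large/long emphasis
    sum(pg^2) / nr,                       # GrayLevelNonUniformity
    sum(pg^2) / nr^2,                     # GrayLevelNonUniformityNormalized
    sum(ps^2) / nr,                       # size NonUniformity
    sum(ps^2) / nr^2,                     # size NonUniformityNormalized
    nr / n_obs,                           # percentage
    sum(rowSums(p) / i^2),                # LowGrayLevel emphasis
    sum(rowSums(p) * i^2),                # HighGrayLevel emphasis
    sum(P / (i2 * j2)) / nr,              # small + low
    sum(P * i2 / j2) / nr,                # small + high
    sum(P * j2 / i2) / nr,                # large + low
    sum(P * i2 * j2) / nr,                # large + high
    sum(p * (matrix(i, nrow(P), ncol(P)) - mu_i)^2),        # GL variance
    sum(p * (matrix(j, nrow(P), ncol(P), byrow = TRUE) - mu_j)^2), # size var
    -sum(xlog2(p))                        # entropy
  )
  names(vals) <- prefix
  vals
}

glrlm_features <- function(P, n_vox, n_dirs = 13) {
  rl_style_features(P, n_vox, n_obs = n_vox * n_dirs, prefix = c(
    "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage",
    "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
    "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
    "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis",
    "GrayLevelVariance", "RunVariance", "RunEntropy"
  ))
}

glszm_features <- function(P, n_vox) {
  rl_style_features(P, n_vox, n_obs = n_vox, prefix = c(
    "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "ZonePercentage",
    "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
    "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
    "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis",
    "GrayLevelVariance", "ZoneVariance", "ZoneEntropy"
  ))
}

gldm_features <- function(P, n_vox) {
  nz <- sum(P)
  if (nz == 0) return(NULL)
  p <- P / nz
  i <- seq_len(nrow(P))
  j <- seq_len(ncol(P))
  i2 <- matrix(i^2, nrow(P), ncol(P))
  j2 <- matrix(j^2, nrow(P), ncol(P), byrow = TRUE)
  pg <- rowSums(P)
  pd <- colSums(P)
  mu_i <- sum(rowSums(p) * i)
  mu_j <- sum(colSums(p) * j)
  c(
    SmallDependenceEmphasis = sum(P / j2) / nz,
    LargeDependenceEmphasis = sum(P * j2) / nz,
    GrayLevelNonUniformity = sum(pg^2) / nz,
    DependenceNonUniformity = sum(pd^2) / nz,
    DependenceNonUniformityNormalized = sum(pd^2) / nz^2,
    GrayLevelVariance = sum(p * (matrix(i, nrow(P), ncol(P)) - mu_i)^2),
    DependenceVariance = sum(p * (matrix(j, nrow(P), ncol(P), byrow = TRUE) - mu_j)^2),
    DependenceEntropy = -sum(xlog2(p)),
    LowGrayLevelEmphasis = sum(rowSums(p) / i^2),
    HighGrayLevelEmphasis = sum(rowSums(p) * i^2),
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i2 * j2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i2 / j2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j2 / i2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i2 * j2) / nz
  )
}

ngtdm_features <- function(tab) {
  p <- tab$p
  s <- tab$s
  lev <- tab$levels
  act <- which(p > 0)
  ngp <- length(act)
  np <- tab$nvp
  if (np == 0) return(NULL)
  sum_ps <- sum(p * s)
  coarseness <- if (sum_ps > 0) 1 / sum_ps else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(p[act], p[act]) * outer(lev[act], lev[act], "-")^2) /
       (ngp * (ngp - 1))) * (sum(s) / np)
  } else 0
  den_busy <- sum(abs(outer(lev[act] * p[act], lev[act] * p[act], "-")))
  busyness <- if (den_busy > 0) sum_ps / den_busy else 0
  complexity <- if (ngp > 0) {
    pi_ <- p[act]; si <- s[act]; li <- lev[act]
    num <- outer(li, li, function(a, b) abs(a - b)) *
      (outer(pi_ * si, rep(1, ngp)) + outer(rep(1, ngp), pi_ * si)) /
      (outer(pi_, rep(1, ngp)) + outer(rep(1, ngp), pi_))
    sum(num) / np
  } else 0
  strength <- if (sum(s) > 0) {
    sum((outer(p[act], rep(1, ngp)) + outer(rep(1, ngp), p[act])) *
          outer(lev[act], lev[act], "-")^2) / sum(s)
  } else 0
  c(Busyness = busyness, Coarseness = coarseness, Complexity = complexity,
    Contrast = contrast, Strength = strength)
}
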