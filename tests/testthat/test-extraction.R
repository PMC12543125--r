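# Feature extraction: registry completeness, closed-form values on toy
# volumes, brute-force matrix oracles, and the filtering/aggregation rules.

test_that("registry covers the full 107-feature set with the documented family sizes", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 107)
  expect_equal(unname(table(reg$family)[c("shape", "firstorder", "glcm",
                                          "gldm", "glrlm", "glszm", "ngtdm")]),
               c(14, 18, 24, 14, 16, 16, 5), ignore_attr = TRUE)
  expect_false(any(duplicated(paste(reg$family, reg$feature))))
  # 26-connectivity halves to exactly 13 unique directions
  dirs <- radiorobust:::unique_directions()
  expect_equal(nrow(dirs), 13)
  expect_equal(nrow(unique(rbind(dirs, -dirs))), 26)
})

test_that("extraction emits 107 records per VOI with closed-form toy values", {
  img <- as_volume(array(7, c(4, 4, 4)), c(1, 1, 1))
  msk <- as_volume(array(1L, c(4, 4, 4)), c(1, 1, 1))
  rec <- extract_features(img, msk, bin_count = 64)
  expect_equal(nrow(rec), 107)
  val <- function(f) rec$value[rec$feature == f]
  # constant VOI: single-bin distribution
  expect_equal(val("firstorder_Entropy"), 0)
  expect_equal(val("firstorder_Variance"), 0)
  expect_equal(val("firstorder_Uniformity"), 1)
  expect_equal(val("firstorder_Mean"), 7)
  expect_equal(rec$value[rec$feature == "firstorder_Energy"], 64 * 49)
  expect_equal(val("shape_VoxelVolume"), 64)
  # constant grey level: one run per voxel line, one zone
  expect_equal(val("glcm_JointEntropy"), 0)
  expect_equal(rec$value[rec$family == "glszm" &
                           rec$feature == "glszm_ZonePercentage"], 1 / 64)
})

test_that("first-order statistics match direct formulas on random values", {
  set.seed(3)
  v <- rnorm(200, 10, 2)
  b <- discretize_fbn(v, 16)
  f <- radiorobust:::firstorder_features(v, b, 2)
  expect_equal(unname(f["Mean"]), mean(v))
  expect_equal(unname(f["Variance"]), mean((v - mean(v))^2))
  expect_equal(unname(f["Skewness"]),
               mean((v - mean(v))^3) / mean((v - mean(v))^2)^1.5)
  expect_equal(unname(f["RootMeanSquared"]), sqrt(mean(v^2)))
  expect_equal(unname(f["TotalEnergy"]), 2 * sum(v^2))
  expect_equal(unname(f["10Percentile"]), quantile(v, 0.1, names = FALSE))
  p <- tabulate(b, 16) / 200
  expect_equal(unname(f["Entropy"]), -sum(ifelse(p > 0, p * log2(p), 0)))
})

test_that("discretization uses the fixed-bin-number convention", {
  v <- c(0, 1, 2, 3, 4)
  expect_equal(discretize_fbn(v, 4), c(1L, 2L, 3L, 4L, 4L))
  expect_equal(discretize_fbn(rep(5, 10), 64), rep(1L, 10))
  expect_equal(max(discretize_fbn(runif(100), 64)), 64L)
})

test_that("GLCM and GLDM matrices match brute-force neighbourhood enumeration", {
  for (seed in 1:3) {
    arr <- random_voi_array(c(5, 4, 3), n_levels = 4, seed = seed)
    if (all(is.na(arr))) next
    P <- radiorobust:::glcm_matrix(arr, 4)
    expect_equal(P, oracle_glcm(arr, 4), ignore_attr = TRUE)
    D <- radiorobust:::gldm_matrix(arr, 4)
    O <- oracle_gldm(arr, 4)
    expect_equal(D[, seq_len(ncol(O))], O, ignore_attr = TRUE)
  }
})

test_that("GLRLM runs are found correctly along all 13 directions", {
  # a 1x1xN line: runs along z only; 12 other directions give unit runs
  arr <- array(NA_integer_, c(1, 1, 6))
  arr[1, 1, ] <- c(1L, 1L, 1L, 2L, 2L, 1L)
  P <- radiorobust:::glrlm_matrix(arr, 2)
  # z-direction: runs (1,len3), (2,len2), (1,len1); the 12 in-plane/diagonal
  # directions each see 6 unit runs (4 of level 1, 2 of level 2)
  expect_equal(P[1, 3], 1)
  expect_equal(P[2, 2], 1)
  expect_equal(P[1, 1], 1 + 12 * 4)
  expect_equal(P[2, 1], 12 * 2)
  # total run length over directions = 13 * voxels
  expect_equal(sum(P %*% seq_len(ncol(P))), 13 * 6)
  # randomized invariant: per-direction run lengths always sum to n voxels
  arr2 <- random_voi_array(c(4, 4, 4), 3, seed = 9)
  P2 <- radiorobust:::glrlm_matrix(arr2, 3)
  expect_equal(sum(P2 %*% seq_len(ncol(P2))), 13 * sum(!is.na(arr2)))
})

test_that("GLSZM zones are 26-connected equal-level components", {
  arr <- array(NA_integer_, c(3, 3, 1))
  arr[, , 1] <- matrix(c(1, 1, 2,
                         2, 1, 2,
                         3, 3, 1), 3, 3, byrow = TRUE)
  # zones: level 1 component {(1,1),(1,2),(2,2),(3,3)} (diagonal-connected),
  # level 2: {(1,3),(2,3)} and {(2,1)}, level 3: {(3,1),(3,2)}
  P <- radiorobust:::glszm_matrix(arr, 3)
  expect_equal(P[1, 4], 1)
  expect_equal(P[2, 2], 1)
  expect_equal(P[2, 1], 1)
  expect_equal(P[3, 2], 1)
  expect_equal(sum(P), 4)
  expect_equal(sum(P %*% seq_len(ncol(P))), sum(!is.na(arr)))
})

test_that("NGTDM occurrence and difference columns match hand computation", {
  arr <- array(NA_integer_, c(3, 1, 1))
  arr[, 1, 1] <- c(1L, 2L, 3L)
  tab <- radiorobust:::ngtdm_table(arr, 3)
  # neighbours: voxel1 sees {2}, voxel2 sees {1,3} (mean 2), voxel3 sees {2}
  expect_equal(tab$p, rep(1 / 3, 3))
  expect_equal(tab$s, c(abs(1 - 2), abs(2 - 2), abs(3 - 2)))
})

test_that("mesh volume approaches the analytic sphere volume", {
  spec <- phantom_spec()
  msk <- make_voi_masks(spec, 256)
  rec <- extract_features(as_volume(array(1, dim(msk$data)), msk$spacing), msk)
  mv <- rec$value[rec$feature == "shape_MeshVolume" & rec$region == "sphere1"]
  expect_equal(mv, 4 / 3 * pi * 18.5^3, tolerance = 0.02)
  # shape features depend on the mask alone: constant across image content
  rec2 <- extract_features(as_volume(array(rnorm(prod(dim(msk$data))),
                                           dim(msk$data)), msk$spacing), msk)
  expect_equal(rec2$value[rec2$family == "shape"],
               rec$value[rec$family == "shape"])
})

test_that("validity filtering excludes a pair across the whole group", {
  base <- expand.grid(region = c("sphere6", "sphere1"),
                      x_value = c(128, 192, 256, 384),
                      stringsAsFactors = FALSE)
  rec <- data.frame(feature = "GrayLevelVariance", family = "glszm",
                    region = base$region, group = "matrix_size",
                    x_value = base$x_value, value = 1,
                    valid = !(base$region == "sphere6" & base$x_value == 128),
                    reason = ifelse(base$region == "sphere6" & base$x_value == 128,
                                    "insufficient-voxels", ""),
                    stringsAsFactors = FALSE)
  out <- filter_invalid(rec)
  expect_false(any(out$records$region == "sphere6"))
  expect_equal(sum(out$records$region == "sphere1"), 4)
  expect_equal(out$log$region, "sphere6")
  expect_match(out$log$reason, "insufficient-voxels")
  # all-valid input passes through untouched
  rec$valid <- TRUE
  expect_equal(nrow(filter_invalid(rec)$records), nrow(rec))
  # a feature invalid everywhere disappears entirely, and is logged
  rec$valid <- FALSE
  out2 <- filter_invalid(rec)
  expect_equal(nrow(out2$records), 0)
  expect_equal(nrow(out2$log), 2)
})

test_that("nuisance aggregation collapses the updates grid to its margins", {
  combos <- expand.grid(iterations = c(1, 2, 3, 4, 5, 6, 8, 10),
                        subsets = c(16, 28, 32))
  rec <- data.frame(feature = "f", family = "glcm", region = "sphere1",
                    group = "osem_updates",
                    x_value = combos$iterations * combos$subsets,
                    value = combos$iterations * 100 + combos$subsets,
                    valid = TRUE, reason = "",
                    iterations = combos$iterations, subsets = combos$subsets,
                    stringsAsFactors = FALSE)
  it <- aggregate_nuisance(rec, "osem_iterations")
  expect_equal(nrow(it), 8)
  expect_equal(sort(it$x_value), c(1, 2, 3, 4, 5, 6, 8, 10))
  expect_equal(it$value[it$x_value == 2], 200 + mean(c(16, 28, 32)))
  su <- aggregate_nuisance(rec, "osem_subsets")
  expect_equal(nrow(su), 3)
  expect_equal(su$value[su$x_value == 16],
               mean(c(1, 2, 3, 4, 5, 6, 8, 10)) * 100 + 16)
  expect_error(aggregate_nuisance(rec[-1, ], "osem_iterations"), "missing")
})

test_that("region covariates come from MeshVolume and Mean", {
  rec <- rbind(
    data.frame(feature = "shape_MeshVolume", family = "shape", region = "r1",
               group = "g", x_value = 1, value = 100, valid = TRUE, reason = ""),
    data.frame(feature = "firstorder_Mean", family = "firstorder", region = "r1",
               group = "g", x_value = 1, value = 9, valid = TRUE, reason = "")
  )
  cov <- region_covariates(rec)
  expect_equal(cov$mesh_volume, 100)
  expect_equal(cov$mean_intensity, 9)
  expect_error(region_covariates(rec[1, ]), "Mean")
  expect_error(region_covariates(rec[0, ]), "empty")
})
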