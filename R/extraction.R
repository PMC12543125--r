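# Feature extraction: propagate VOI labels to a reconstructed volume and
# compute the 107-feature IBSI-style set per VOI, with the study's
# discretization (fixed bin number 64) and aggregation (matrices summed over
# the 13 unique 3D directions) conventions.

FEATURE_FAMILIES <- c("shape", "firstorder", "glcm", "gldm", "glrlm",
                      "glszm", "ngtdm")

#' The 107-feature registry
#'
#' Names and families of the standard feature set: 14 shape, 18 first-order,
#' 24 GLCM, 14 GLDM, 16 GLRLM, 16 GLSZM and 5 NGTDM features.
#'
#' @return Data frame with columns `family` and `feature`.
#' @examples
#' table(feature_registry()$family)
#' @export
feature_registry <- function() {
  reg <- list(
    shape = c("MeshVolume", "VoxelVolume", "SurfaceArea",
              "SurfaceVolumeRatio", "Sphericity", "MajorAxisLength",
              "MinorAxisLength", "LeastAxisLength", "Elongation", "Flatness",
              "Maximum3DDiameter", "Maximum2DDiameterSlice",
              "Maximum2DDiameterColumn", "Maximum2DDiameterRow"),
    firstorder = c("Energy", "TotalEnergy", "Entropy", "Minimum",
                   "10Percentile", "90Percentile", "Maximum", "Mean",
                   "Median", "InterquartileRange", "Range",
                   "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
                   "RootMeanSquared", "Skewness", "Kurtosis", "Variance",
                   "Uniformity"),
    glcm = c("Autocorrelation", "JointAverage", "ClusterProminence",
             "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
             "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn",
             "Id", "Idn", "InverseVariance", "MaximumProbability",
             "SumAverage", "SumEntropy", "SumSquares", "MCC"),
    gldm = c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
             "GrayLevelNonUniformity", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "GrayLevelVariance",
             "DependenceVariance", "DependenceEntropy",
             "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
             "SmallDependenceLowGrayLevelEmphasis",
             "SmallDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis",
             "LargeDependenceHighGrayLevelEmphasis"),
    glrlm = c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
              "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
              "RunLengthNonUniformityNormalized", "RunPercentage",
              "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
              "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
              "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis",
              "GrayLevelVariance", "RunVariance", "RunEntropy"),
    glszm = c("SmallAreaEmphasis", "LargeAreaEmphasis",
              "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
              "ZonePercentage", "LowGrayLevelZoneEmphasis",
              "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
              "SmallAreaHighGrayLevelEmphasis",
              "LargeAreaLowGrayLevelEmphasis",
              "LargeAreaHighGrayLevelEmphasis", "GrayLevelVariance",
              "ZoneVariance", "ZoneEntropy"),
    ngtdm = c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
  )
  data.frame(
    family = rep(names(reg), lengths(reg)),
    feature = unlist(reg, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

# One VOI: crop to bounding box, discretize, compute all families.
# Returns data.frame(family, feature, value, valid, reason).
extract_voi <- function(image, mask_arr, label, spacing, bin_count) {
  reg <- feature_registry()
  lin <- which(mask_arr == label)
  blank <- function(reason, families = FEATURE_FAMILIES) {
    out <- reg[reg$family %in% families, ]
    out$value <- NA_real_
    out$valid <- FALSE
    out$reason <- reason
    out
  }
  if (length(lin) == 0) {
    return(blank("empty-voi"))
  }
  coords <- arrayInd(lin, dim(mask_arr))
  rng <- apply(coords, 2, range)
  sub_img <- image[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                   rng[1, 3]:rng[2, 3], drop = FALSE]
  sub_msk <- mask_arr[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                      rng[1, 3]:rng[2, 3], drop = FALSE] == label
  vals <- sub_img[sub_msk]
  n <- length(vals)
  rows <- list()
  emit <- function(family, v) {
    want <- reg$feature[reg$family == family]
    if (is.null(v)) {
      rows[[family]] <<- blank("matrix-not-formable", family)
      return(invisible())
    }
    v <- v[want]
    ok <- is.finite(v)
    rows[[family]] <<- data.frame(
      family = family, feature = want, value = as.numeric(v), valid = ok,
      reason = ifelse(ok, "", "undefined-value"), stringsAsFactors = FALSE
    )
  }
  emit("shape", shape_features(sub_msk * 1L, spacing))
  binned <- discretize_fbn(vals, bin_count)
  emit("firstorder", firstorder_features(vals, binned, prod(spacing)))
  if (n < 2) {
    for (f in c("glcm", "gldm", "glrlm", "glszm", "ngtdm")) {
      rows[[f]] <- blank("insufficient-voxels", f)
    }
  } else {
    arr <- array(NA_integer_, dim(sub_msk))
    arr[sub_msk] <- binned
    nl <- max(binned)
    emit("glcm", glcm_features(glcm_matrix(arr, nl)))
    emit("gldm", gldm_features(gldm_matrix(arr, nl), n))
    emit("glrlm", glrlm_features(glrlm_matrix(arr, nl), n))
    emit("glszm", glszm_features(glszm_matrix(arr, nl), n))
    emit("ngtdm", ngtdm_features(ngtdm_table(arr, nl)))
  }
  out <- do.call(rbind, rows[FEATURE_FAMILIES])
  rownames(out) <- NULL
  out
}

#' Extract the 107-feature set for every VOI of a label map
#'
#' @param image An [as_volume()] image.
#' @param mask A label map from [make_voi_masks()] (or an `rr_volume` of
#'   integer labels with a `region_labels` attribute).
#' @param bin_count Fixed bin number for intensity discretization
#'   (default 64).
#' @param group,x_value Optional bookkeeping columns stamped on every record.
#' @return Long data frame: `feature`, `family`, `region`, `group`,
#'   `x_value`, `value`, `valid`, `reason` — 107 rows per VOI.
#' @examples
#' \donttest{
#' spec <- phantom_spec()
#' img <- build_activity_map(spec, 128)
#' msk <- suppressWarnings(make_voi_masks(spec, 128))
#' feats <- extract_features(img, msk)
#' nrow(feats) / 9  # 107
#' }
#' @export
extract_features <- function(image, mask, bin_count = 64, group = NA_character_,
                             x_value = NA_real_) {
  if (!identical(dim(image$data), dim(mask$data))) {
    rr_abort("image and mask must share a grid")
  }
  labels <- attr(mask, "region_labels")
  if (is.null(labels)) {
    lv <- sort(unique(mask$data[mask$data > 0]))
    labels <- stats::setNames(lv, paste0("region", lv))
  }
  out <- lapply(seq_along(labels), function(i) {
    rec <- extract_voi(image$data, mask$data, labels[i], image$spacing,
                       bin_count)
    rec$region <- names(labels)[i]
    rec
  })
  out <- do.call(rbind, out)
  # family-qualified names: several families share short names (Contrast,
  # GrayLevelVariance, ...), so the feature id must carry the family
  out$feature <- paste(out$family, out$feature, sep = "_")
  out$group <- group
  out$x_value <- x_value
  rownames(out) <- NULL
  out[, c("feature", "family", "region", "group", "x_value", "value",
          "valid", "reason")]
}

#' Exclude (feature, region) pairs invalid anywhere in a group
#'
#' Within each group, any (feature, region) pair invalid at one or more
#' levels is excluded from all levels of that group so downstream
#' regions x levels tables stay complete. Every exclusion is logged.
#'
#' @param records Long feature table across the levels of one or more
#'   groups.
#' @return List with `records` (invalid pairs removed) and `log` (one row
#'   per excluded feature x region x group with the reasons seen).
#' @export
filter_invalid <- function(records) {
  bad <- unique(records[!records$valid,
                        c("feature", "family", "region", "group")])
  if (nrow(bad) == 0) {
    return(list(records = records, log = bad))
  }
  reasons <- vapply(seq_len(nrow(bad)), function(i) {
    r <- records$reason[!records$valid &
                          records$feature == bad$feature[i] &
                          records$region == bad$region[i] &
                          records$group == bad$group[i]]
    paste(unique(r[nzchar(r)]), collapse = ";")
  }, character(1))
  bad$reason <- reasons
  key <- function(df) paste(df$feature, df$region, df$group, sep = "\r")
  keep <- !(key(records) %in% key(bad))
  list(records = records[keep, , drop = FALSE], log = bad)
}

#' Average out the nuisance dimension of the updates grid
#'
#' The iterations and subsets investigation groups are marginal views of the
#' 24 iterations x subsets combinations: per feature x region, values are
#' averaged over the 3 subset schemes for each iteration count (or over the
#' 8 iteration schemes for each subset count).
#'
#' @param updates_records Feature records of the updates group, carrying
#'   `iterations` and `subsets` columns.
#' @param group `"osem_iterations"` or `"osem_subsets"`.
#' @return Feature records for the marginal group, `x_value` set to the kept
#'   dimension.
#' @export
aggregate_nuisance <- function(updates_records, group) {
  group <- match_label(group, c("osem_iterations", "osem_subsets"),
                       "aggregation group")
  keep <- if (group == "osem_iterations") "iterations" else "subsets"
  drop <- setdiff(c("iterations", "subsets"), keep)
  if (!all(c("iterations", "subsets") %in% names(updates_records))) {
    rr_abort("updates records must carry iterations and subsets columns")
  }
  full <- table(unique(updates_records[, c("iterations", "subsets")]))
  if (any(full == 0)) {
    miss <- which(full == 0, arr.ind = TRUE)
    rr_abort(sprintf("missing updates cell: iterations %s x subsets %s",
                     rownames(full)[miss[1, 1]], colnames(full)[miss[1, 2]]))
  }
  sp <- split(updates_records,
              list(updates_records$feature, updates_records$region,
                   updates_records[[keep]]), drop = TRUE)
  out <- lapply(sp, function(s) {
    data.frame(
      feature = s$feature[1], family = s$family[1], region = s$region[1],
      group = group, x_value = as.numeric(s[[keep]][1]),
      level = as.character(s[[keep]][1]),
      value = mean(s$value), valid = all(s$valid),
      reason = paste(unique(s$reason[nzchar(s$reason)]), collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-region volume and intensity covariates
#'
#' Pulls the shape `MeshVolume` and first-order `Mean` features out of a
#' feature table as the per-region volume and intensity covariates used by
#' the mixed-effects attribution stage.
#'
#' @param records Long feature table.
#' @return Data frame `region`, `group`, `x_value`, `mesh_volume`,
#'   `mean_intensity`.
#' @export
region_covariates <- function(records) {
  if (nrow(records) == 0) rr_abort("empty feature table")
  mv <- records[records$feature == "shape_MeshVolume", ]
  mi <- records[records$feature == "firstorder_Mean", ]
  if (nrow(mv) == 0 || nrow(mi) == 0) {
    rr_abort("records must contain shape MeshVolume and first-order Mean")
  }
  out <- merge(
    mv[, c("region", "group", "x_value", "value")],
    mi[, c("region", "group", "x_value", "value")],
    by = c("region", "group", "x_value"), suffixes = c("_vol", "_int")
  )
  names(out)[names(out) == "value_vol"] <- "mesh_volume"
  names(out)[names(out) == "value_int"] <- "mean_intensity"
  out
}
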