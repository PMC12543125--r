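# Investigation-group grid: the standard set of 94 acquisition/reconstruction
# setting variations, organised in 9 groups that each vary one parameter while
# holding the others fixed.

ZFILTER_LEVELS <- c("None", "Light", "Standard", "Heavy")
ALGORITHM_LEVELS <- c("OSEM", "TOF-OSEM", "OSEM+PSF", "TOF-OSEM+PSF",
                      "BPL", "TOF-BPL")
MATRIX_SIZES <- c(128L, 192L, 256L, 384L)

GROUP_NAMES <- c("acquisition_time", "matrix_size", "z_filter",
                 "gaussian_fwhm", "bpl_beta", "osem_updates",
                 "osem_iterations", "osem_subsets", "algorithm")

# Baseline reconstruction shared by most groups: 3 min/bed TOF-OSEM 2x28 on a
# 256 matrix with a 5 mm Gaussian and no axial filter.
baseline_setting <- function() {
  list(
    acquisition_time = 3, matrix_size = 256L, z_filter = "None",
    gaussian_fwhm = 5, algorithm = "TOF-OSEM",
    iterations = 2L, subsets = 28L, beta = NA_real_
  )
}

#' Default investigation groups
#'
#' Returns the frozen default definition of the nine investigation groups:
#' which acquisition/reconstruction parameter each varies, its ordered levels,
#' and the constants every other field is held at. Level counts are
#' 11, 4, 4, 21, 13, 24, 8, 3 and 6 (94 variations in total). The
#' iterations and subsets groups are marginal views of the 24
#' iterations-x-subsets combinations: each carries an `aggregate_over` tag
#' naming the field that is averaged out downstream.
#'
#' @return Named list of investigation-group definitions. Each element has
#'   `name`, `varied_parameter`, `levels`, `constants` and (for the two
#'   marginal groups) `aggregate_over`.
#' @examples
#' names(investigation_groups())
#' investigation_groups()$acquisition_time$levels
#' @export
investigation_groups <- function() {
  base <- baseline_setting()
  const <- function(drop, ...) {
    out <- utils::modifyList(base, list(...))
    out[setdiff(names(out), drop)]
  }
  updates_levels <- expand.grid(
    subsets = c(16L, 28L, 32L),
    iterations = c(1L, 2L, 3L, 4L, 5L, 6L, 8L, 10L)
  )[, c("iterations", "subsets")]
  updates_levels <- updates_levels[order(updates_levels$iterations,
                                         updates_levels$subsets), ]
  list(
    acquisition_time = list(
      name = "acquisition_time", varied_parameter = "acquisition_time",
      levels = c(1, 1.5, 2, 3, 4, 5, 6, 8, 10, 12.5, 15),
      constants = const("acquisition_time")
    ),
    matrix_size = list(
      name = "matrix_size", varied_parameter = "matrix_size",
      levels = MATRIX_SIZES,
      constants = const("matrix_size")
    ),
    z_filter = list(
      name = "z_filter", varied_parameter = "z_filter",
      levels = ZFILTER_LEVELS,
      constants = const("z_filter")
    ),
    gaussian_fwhm = list(
      name = "gaussian_fwhm", varied_parameter = "gaussian_fwhm",
      levels = seq(0, 10, by = 0.5),
      constants = const("gaussian_fwhm")
    ),
    bpl_beta = list(
      name = "bpl_beta", varied_parameter = "beta",
      levels = c(50, 100, 150, 200, 250, 300, 350, 400, 500, 600, 700, 800, 1000),
      constants = const("beta", algorithm = "TOF-BPL", gaussian_fwhm = 0)
    ),
    osem_updates = list(
      name = "osem_updates", varied_parameter = "updates",
      levels = lapply(seq_len(nrow(updates_levels)), function(i)
        c(iterations = updates_levels$iterations[i],
          subsets = updates_levels$subsets[i])),
      constants = const(c("iterations", "subsets"))
    ),
    osem_iterations = list(
      name = "osem_iterations", varied_parameter = "iterations",
      levels = c(1L, 2L, 3L, 4L, 5L, 6L, 8L, 10L),
      constants = const(c("iterations", "subsets")),
      aggregate_over = "subsets"
    ),
    osem_subsets = list(
      name = "osem_subsets", varied_parameter = "subsets",
      levels = c(16L, 28L, 32L),
      constants = const(c("iterations", "subsets")),
      aggregate_over = "iterations"
    ),
    algorithm = list(
      name = "algorithm", varied_parameter = "algorithm",
      levels = ALGORITHM_LEVELS,
      constants = const("algorithm", gaussian_fwhm = 0, beta = 350)
    )
  )
}

validate_setting <- function(s) {
  if (!is.na(s$acquisition_time) && s$acquisition_time <= 0) {
    rr_abort("acquisition_time must be positive",
             class = "radiorobust_validation_error")
  }
  if (!s$matrix_size %in% MATRIX_SIZES) {
    rr_abort(sprintf("matrix_size %s not in documented set {%s}",
                     s$matrix_size, paste(MATRIX_SIZES, collapse = ", ")),
             class = "radiorobust_validation_error")
  }
  if (!is.na(s$gaussian_fwhm) && s$gaussian_fwhm < 0) {
    rr_abort("gaussian_fwhm must be >= 0",
             class = "radiorobust_validation_error")
  }
  if (!is.na(s$iterations) && s$iterations < 1) {
    rr_abort("iterations must be >= 1", class = "radiorobust_validation_error")
  }
  if (!is.na(s$subsets) && s$subsets < 1) {
    rr_abort("subsets must be >= 1", class = "radiorobust_validation_error")
  }
  if (grepl("BPL", s$algorithm) && (is.na(s$beta) || s$beta <= 0)) {
    rr_abort("beta must be positive for BPL-type algorithms",
             class = "radiorobust_validation_error")
  }
  invisible(s)
}

#' Enumerate fully specified settings for the investigation groups
#'
#' Expands each requested investigation group into one fully specified
#' acquisition/reconstruction setting per level (constants applied). The
#' default nine groups expand to 94 settings. The iterations and subsets
#' groups are marginal over the updates combinations, so their
#' aggregated-out field is `NA` in the emitted settings and their values are
#' derived downstream by [aggregate_nuisance()].
#'
#' @param groups Character vector of group names to include (default all
#'   nine); matching is case-insensitive. A zero-length vector yields an
#'   empty grid.
#' @param definitions Group definitions, defaulting to
#'   [investigation_groups()]; supply a modified list to add custom groups.
#' @return A data frame with one row per setting: `group`, `level_index`,
#'   `x_value` (numeric encoding of the varied level; z-filters encoded via
#'   [encode_zfilter()], updates as iterations x subsets, algorithms as their
#'   1-based level index), `level_label`, and the full setting fields
#'   (`acquisition_time`, `matrix_size`, `z_filter`, `gaussian_fwhm`,
#'   `algorithm`, `iterations`, `subsets`, `beta`).
#' @examples
#' g <- build_grid()
#' nrow(g)                      # 94
#' table(g$group)
#' @export
build_grid <- function(groups = NULL, definitions = investigation_groups()) {
  if (is.null(groups)) groups <- names(definitions)
  if (length(groups) == 0) {
    return(empty_grid())
  }
  groups <- match_label(groups, names(definitions), what = "investigation group")
  rows <- lapply(groups, function(gn) {
    def <- definitions[[gn]]
    lv <- def$levels
    n <- length(lv)
    out <- lapply(seq_len(n), function(i) {
      s <- def$constants
      level <- if (is.list(lv)) lv[[i]] else lv[i]
      if (def$varied_parameter == "updates") {
        s$iterations <- as.integer(level[["iterations"]])
        s$subsets <- as.integer(level[["subsets"]])
        x <- s$iterations * s$subsets
        lab <- sprintf("%dx%d", s$iterations, s$subsets)
      } else if (def$varied_parameter == "z_filter") {
        s$z_filter <- match_label(level, ZFILTER_LEVELS, "z-filter")
        x <- encode_zfilter(level)
        lab <- s$z_filter
      } else if (def$varied_parameter == "algorithm") {
        s$algorithm <- match_label(level, ALGORITHM_LEVELS, "algorithm")
        x <- i  # categorical; index used only for bookkeeping
        lab <- s$algorithm
      } else {
        s[[def$varied_parameter]] <- level
        x <- as.numeric(level)
        lab <- format(level)
      }
      # marginal groups leave their aggregated-out field unspecified
      if (!is.null(def$aggregate_over)) s[[def$aggregate_over]] <- NA_integer_
      if (def$varied_parameter == "iterations") s$iterations <- as.integer(level)
      if (def$varied_parameter == "subsets") s$subsets <- as.integer(level)
      validate_setting(s)
      data.frame(
        group = gn, level_index = i, x_value = x, level_label = lab,
        acquisition_time = s$acquisition_time,
        matrix_size = as.integer(s$matrix_size),
        z_filter = s$z_filter, gaussian_fwhm = s$gaussian_fwhm,
        algorithm = s$algorithm,
        iterations = as.integer(s$iterations),
        subsets = as.integer(s$subsets),
        beta = as.numeric(s$beta),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_grid <- function() {
  data.frame(
    group = character(), level_index = integer(), x_value = numeric(),
    level_label = character(), acquisition_time = numeric(),
    matrix_size = integer(), z_filter = character(), gaussian_fwhm = numeric(),
    algorithm = character(), iterations = integer(), subsets = integer(),
    beta = numeric(), stringsAsFactors = FALSE
  )
}

#' Encode a z-axis filter label as its kernel weight
#'
#' Maps the categorical axial filter strength to the numeric weight of its
#' three-point smoothing kernel: None = 1, Light = 2, Standard = 4, Heavy = 6.
#' Matching is case-insensitive after trimming.
#'
#' @param label Character vector of filter labels.
#' @return Numeric vector of kernel weights.
#' @examples
#' encode_zfilter(c("None", "heavy"))
#' @export
encode_zfilter <- function(label) {
  canon <- match_label(label, ZFILTER_LEVELS, what = "z-filter label")
  c(None = 1, Light = 2, Standard = 4, Heavy = 6)[canon]
}

# Groups whose x-axis is rescaled before curve fitting so that the reciprocal
# and log model families stay away from division by zero: acquisition time,
# z-filter kernel weight and OSEM iterations are multiplied by 10; Gaussian
# filter widths are shifted by 2 mm. All other groups are untransformed.
RESCALE_X10 <- c("acquisition_time", "z_filter", "osem_iterations")
RESCALE_SHIFT2 <- "gaussian_fwhm"

#' Rescale parameter values for curve fitting and correction
#'
#' @param group_name Investigation group the values belong to.
#' @param x Numeric parameter values (z-filters already encoded as kernel
#'   weights).
#' @return Transformed values: `x * 10` for acquisition time, z-filter weight
#'   and OSEM iterations; `x + 2` for Gaussian filter width; `x` unchanged
#'   otherwise.
#' @examples
#' rescale_x("gaussian_fwhm", 0)      # 2
#' rescale_x("acquisition_time", 1.5) # 15
#' @export
rescale_x <- function(group_name, x) {
  group_name <- match_label(group_name, GROUP_NAMES, "investigation group")
  if (!is.numeric(x)) rr_abort("`x` must be numeric",
                               class = "radiorobust_validation_error")
  out <- if (group_name %in% RESCALE_X10) x * 10
    else if (group_name %in% RESCALE_SHIFT2) x + 2
    else x
  if (group_name != "algorithm" && any(out <= 0, na.rm = TRUE)) {
    warning(sprintf(
      "rescale_x(%s): %d non-positive transformed value(s); log/reciprocal fits will be inadmissible there",
      group_name, sum(out <= 0, na.rm = TRUE)
    ))
    attr(out, "nonpositive") <- which(out <= 0)
  }
  out
}
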