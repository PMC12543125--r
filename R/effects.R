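# Attribution of feature variability to the varied parameter versus region
# volume and intensity, via linear mixed-effects models with per-region
# random intercepts and parameter slopes. Response and continuous predictors
# are z-standardized per feature x group so fixed-effect coefficients are
# comparable across features.

zstd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Fit the volume/intensity attribution model for one feature x group
#'
#' Fits `value ~ parameter + volume + intensity` with per-region random
#' intercepts and random parameter slopes (numeric parameters), or
#' `value ~ factor(parameter) + volume + intensity` with random intercepts
#' only for the categorical algorithm group. p-values come from the
#' Satterthwaite approximation (lmerTest). All continuous variables are
#' z-standardized before fitting.
#'
#' @param values Data frame with columns `region`, `x_value`, `value` for
#'   one feature x group (z-filters already encoded numerically).
#' @param covariates Output of [region_covariates()] for the same group
#'   (matched on region and x_value).
#' @param group Investigation-group name; `"algorithm"` switches to the
#'   categorical specification.
#' @param feature Feature name stamped on the record.
#' @return One-row data frame: coefficients and p-values for `parameter`,
#'   `volume`, `intensity`, significance flags at 0.05, `categorical` and
#'   `converged` flags.
#' @export
fit_feature_effects <- function(values, covariates, group,
                                feature = "feature") {
  d <- merge(values, covariates[, c("region", "x_value", "mesh_volume",
                                    "mean_intensity")],
             by = c("region", "x_value"))
  if (length(unique(d$region)) < 2) {
    rr_abort("random effects need >= 2 regions")
  }
  if (length(unique(d$x_value)) < 3) {
    rr_abort("need >= 3 parameter levels")
  }
  categorical <- identical(group, "algorithm")
  d$y <- zstd(d$value)
  d$vol <- zstd(d$mesh_volume)
  d$int <- zstd(d$mean_intensity)
  fit <- NULL
  conv <- TRUE
  if (categorical) {
    d$par <- factor(d$x_value)
    form <- y ~ par + vol + int + (1 | region)
  } else {
    d$par <- zstd(d$x_value)
    form <- y ~ par + vol + int + (1 + par | region)
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = d,
                     control = lme4::lmerControl(check.conv.singular = "ignore",
                                                 calc.derivs = FALSE))
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(data.frame(
      feature = feature, group = group,
      coef_parameter = NA_real_, p_parameter = NA_real_,
      coef_volume = NA_real_, p_volume = NA_real_,
      coef_intensity = NA_real_, p_intensity = NA_real_,
      sig_parameter = NA, sig_volume = NA, sig_intensity = NA,
      categorical = categorical, converged = FALSE,
      stringsAsFactors = FALSE
    ))
  }
  cf <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
  if (is.null(cf) || !"Pr(>|t|)" %in% colnames(cf)) conv <- FALSE
  pull <- function(rows) {
    rows <- rows[rows %in% rownames(cf)]
    if (!length(rows) || !conv) return(c(NA_real_, NA_real_))
    # categorical parameter: keep the largest-magnitude level contrast
    i <- rows[which.max(abs(cf[rows, "Estimate"]))]
    c(cf[i, "Estimate"], cf[i, "Pr(>|t|)"])
  }
  par_rows <- if (categorical) grep("^par", rownames(cf), value = TRUE) else "par"
  pp <- pull(par_rows)
  pv <- pull("vol")
  pi_ <- pull("int")
  data.frame(
    feature = feature, group = group,
    coef_parameter = pp[1], p_parameter = pp[2],
    coef_volume = pv[1], p_volume = pv[2],
    coef_intensity = pi_[1], p_intensity = pi_[2],
    sig_parameter = is.finite(pp[2]) && pp[2] < 0.05,
    sig_volume = is.finite(pv[2]) && pv[2] < 0.05,
    sig_intensity = is.finite(pi_[2]) && pi_[2] < 0.05,
    categorical = categorical, converged = conv,
    stringsAsFactors = FALSE
  )
}

#' Attribution models for every feature of a group
#'
#' @param records Filtered feature table for one group (texture/first-order
#'   features; shape features of the covariates are consumed separately).
#' @param covariates [region_covariates()] table for the group.
#' @param group Group name; for the z-filter group `x_value` should already
#'   be the encoded kernel weight.
#' @return Data frame of [fit_feature_effects()] records, one per feature.
#' @export
assess_effects <- function(records, covariates, group) {
  feats <- unique(records$feature[records$valid])
  out <- lapply(feats, function(f) {
    sub <- records[records$feature == f & records$valid,
                   c("region", "x_value", "value")]
    tryCatch(fit_feature_effects(sub, covariates, group, feature = f),
             error = function(e) NULL)
  })
  out <- do.call(rbind, out)
  if (!is.null(out)) rownames(out) <- NULL
  out
}
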