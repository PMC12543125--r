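# Image-domain surrogate for acquisition/reconstruction effects. Rather than
# reconstructing sinograms, the simulator imposes the controllable first- and
# second-moment consequences of each setting on the ideal activity map:
# grid resampling, quadrature-combined Gaussian resolution loss, a 3-point
# axial kernel, and additive count-dependent Gaussian noise.

#' Effect-model constants for the reconstruction surrogate
#'
#' The surrogate is calibrated for direction, not scanner-accurate magnitude:
#' heavier smoothing settings always smooth more, shorter acquisitions and
#' more algorithm updates are always noisier.
#'
#' @param noise_sigma0 Background noise SD (kBq/mL) at the reference
#'   acquisition time and update count.
#' @param reference_time Reference acquisition time, min/bed.
#' @param reference_updates Reference iterations x subsets product.
#' @param update_noise_exponent Exponent of the updates/reference ratio in
#'   the noise SD.
#' @param base_fwhm Intrinsic reconstruction resolution, mm FWHM.
#' @param beta_fwhm_max,beta_fwhm_decay Penalised-likelihood smoothing:
#'   effective extra FWHM `beta_fwhm_max * (1 - exp(-beta/beta_fwhm_decay))`
#'   mm, increasing in the penalisation factor.
#' @param psf_contrast_gain Resolution-recovery factor; PSF modelling divides
#'   the intrinsic FWHM by this gain.
#' @param tof_noise_factor Multiplier (< 1) on noise SD when time-of-flight
#'   information is used.
#' @return Named list of constants.
#' @export
effect_model <- function(noise_sigma0 = 0.5,
                         reference_time = 3,
                         reference_updates = 56,
                         update_noise_exponent = 0.5,
                         base_fwhm = 4.5,
                         beta_fwhm_max = 7,
                         beta_fwhm_decay = 350,
                         psf_contrast_gain = 1.05,
                         tof_noise_factor = 0.85) {
  out <- as.list(environment())
  if (any(vapply(out, function(v) !is.numeric(v) || !is.finite(v), TRUE))) {
    rr_abort("all effect-model constants must be finite numbers",
             class = "radiorobust_config_error")
  }
  out
}

# Total resolution FWHM (mm) implied by a setting: intrinsic resolution
# (sharpened by PSF modelling), explicit post-filter, and the penalised-
# likelihood smoothing term, combined in quadrature.
setting_fwhm <- function(s, model) {
  base <- model$base_fwhm
  if (grepl("PSF", s$algorithm)) base <- base / model$psf_contrast_gain
  g <- if (is.na(s$gaussian_fwhm)) 0 else s$gaussian_fwhm
  b <- if (grepl("BPL", s$algorithm)) {
    model$beta_fwhm_max * (1 - exp(-s$beta / model$beta_fwhm_decay))
  } else 0
  sqrt(base^2 + g^2 + b^2)
}

# Noise SD (kBq/mL) implied by a setting.
setting_noise_sd <- function(s, model) {
  sd <- model$noise_sigma0 * sqrt(model$reference_time / s$acquisition_time)
  if (!grepl("BPL", s$algorithm) && !is.na(s$iterations) && !is.na(s$subsets)) {
    sd <- sd * (s$iterations * s$subsets / model$reference_updates)^
      model$update_noise_exponent
  }
  if (grepl("TOF", s$algorithm)) sd <- sd * model$tof_noise_factor
  sd
}

# Circular separable Gaussian smoothing transfer function (one 3D FFT
# convolution; the uniform background makes the wraparound inconsequential).
# The optional 3-point axial kernel [w, 1-2w, w] is folded into the same
# transfer function.
transfer_function <- function(d, spacing, sigma_mm, z_side_weight = 0) {
  per_axis <- lapply(1:3, function(ax) {
    n <- d[ax]
    k <- 0:(n - 1)
    f <- ifelse(k <= n / 2, k, k - n) / (n * spacing[ax])
    h <- exp(-2 * pi^2 * sigma_mm[ax]^2 * f^2)
    if (ax == 3 && z_side_weight > 0) {
      w <- z_side_weight
      h <- h * ((1 - 2 * w) + 2 * w * cos(2 * pi * f * spacing[ax]))
    }
    h
  })
  outer(outer(per_axis[[1]], per_axis[[2]]), per_axis[[3]])
}

# Trilinear resample of a volume onto a new grid covering the same physical
# extent (same centre), e.g. a different transaxial matrix size.
resample_volume <- function(vol, new_dim) {
  d <- dim(vol$data)
  new_spacing <- d * vol$spacing / new_dim
  # fractional source index of each target voxel centre, clamped to the grid
  g <- lapply(1:3, function(ax) {
    centres <- (seq_len(new_dim[ax]) - 0.5) * new_spacing[ax]
    pmin(pmax(centres / vol$spacing[ax] + 0.5, 1), d[ax])
  })
  lo <- lapply(1:3, function(ax) pmin(floor(g[[ax]]), d[ax] - 1L))
  w <- lapply(1:3, function(ax) g[[ax]] - lo[[ax]])
  arr <- vol$data
  out <- array(0, new_dim)
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    xi <- lo[[1]] + bx
    yi <- lo[[2]] + by
    zi <- lo[[3]] + bz
    wx <- if (bx == 0) 1 - w[[1]] else w[[1]]
    wy <- if (by == 0) 1 - w[[2]] else w[[2]]
    wz <- if (bz == 0) 1 - w[[3]] else w[[3]]
    out <- out + arr[xi, yi, zi, drop = FALSE] * outer(outer(wx, wy), wz)
  }
  as_volume(out, new_spacing)
}

#' Simulate a reconstruction from the ideal activity map
#'
#' Applies, in order: (1) resampling to the setting's matrix grid if needed;
#' (2) 3D Gaussian smoothing at the quadrature-combined FWHM implied by the
#' algorithm, post-filter and penalisation factor; (3) the 3-point axial
#' kernel selected by the z-filter (identity for "None"); (4) additive
#' Gaussian noise whose SD scales as acquisition time to the power -1/2 and
#' with the algorithm's update count. Deterministic given `seed`.
#'
#' @param activity Noise-free activity [as_volume()] (from
#'   [build_activity_map()]).
#' @param setting One row of [build_grid()] (or an equivalent list of
#'   setting fields).
#' @param model [effect_model()] constants.
#' @param seed Integer seed for the noise stream.
#' @return An `rr_volume` with the simulated reconstruction.
#' @export
simulate_reconstruction <- function(activity, setting, model = effect_model(),
                                    seed) {
  s <- as.list(setting)
  needed <- c("acquisition_time", "z_filter", "gaussian_fwhm", "algorithm")
  miss <- setdiff(needed, names(s))
  if (length(miss)) {
    rr_abort(paste("setting is missing fields:", paste(miss, collapse = ", ")),
             class = "radiorobust_config_error")
  }
  need_model <- c("noise_sigma0", "reference_time", "base_fwhm",
                  "tof_noise_factor", "psf_contrast_gain")
  if (length(setdiff(need_model, names(model)))) {
    rr_abort("effect model is missing constants; use effect_model()",
             class = "radiorobust_config_error")
  }
  vol <- activity
  if (!is.null(s$matrix_size) && !is.na(s$matrix_size) &&
      dim(vol)[1] != s$matrix_size) {
    vol <- resample_volume(vol, c(s$matrix_size, s$matrix_size, dim(vol)[3]))
  }
  fwhm <- setting_fwhm(s, model)
  sigma <- rep(fwhm / (2 * sqrt(2 * log(2))), 3)
  c_weight <- encode_zfilter(s$z_filter)
  # axial kernel [c-1, c+1, c-1]/(3c-1): identity at weight 1, monotonically
  # heavier axial smoothing as the encoded strength grows
  side <- (c_weight - 1) / (3 * c_weight - 1)
  smooth <- vol$data
  if (fwhm > 0 || side > 0) {
    tf <- transfer_function(dim(smooth), vol$spacing, sigma,
                            z_side_weight = side)
    smooth <- Re(fft(fft(smooth) * tf, inverse = TRUE)) / length(smooth)
  }
  sd_noise <- setting_noise_sd(s, model)
  out <- with_rr_seed(seed, {
    if (sd_noise > 0) {
      smooth + array(stats::rnorm(length(smooth), sd = sd_noise), dim(smooth))
    } else {
      smooth
    }
  })
  as_volume(out, vol$spacing)
}

#' Simulate a feature table with known parametric structure
#'
#' Generates per-region feature values `v = alpha_r * g(x) + beta_r + eps`
#' for a chosen model family, used to verify that the correction engine
#' recovers the generative family and flattens the parameter dependence.
#' The true per-region coefficients are attached as the `truth` attribute.
#'
#' @param family Generative family, one of [model_families()].
#' @param group Investigation group whose x-rescaling applies.
#' @param x Raw parameter levels (rescaled internally via [rescale_x()]).
#' @param n_regions Number of regions.
#' @param alpha_range,beta_range Ranges the per-region slope/offset are drawn
#'   from (uniform). A zero-width `beta_range` gives the shared-offset case
#'   the correction removes exactly.
#' @param sigma Additive Gaussian noise SD on each value.
#' @param seed Integer seed.
#' @param feature Feature name recorded in the table.
#' @return Long-format data frame with columns `feature`, `family`,
#'   `region`, `group`, `x_value`, `value`, `valid`.
#' @examples
#' tab <- simulate_feature_values("a/x+b", "bpl_beta", x = c(50, 100, 200),
#'                                n_regions = 3, sigma = 0, seed = 1)
#' head(tab)
#' @export
simulate_feature_values <- function(family, group, x, n_regions = 9,
                                    alpha_range = c(0.8, 1.2),
                                    beta_range = c(1, 1),
                                    sigma = 0.05, seed = 1,
                                    feature = "synthetic_feature") {
  family <- match_label(family, model_families(), "model family")
  if (sigma < 0) rr_abort("sigma must be >= 0",
                          class = "radiorobust_validation_error")
  if (n_regions < 2) rr_abort("need at least 2 regions",
                              class = "radiorobust_validation_error")
  xr <- rescale_x(group, x)
  if (any(xr <= 0)) rr_abort("rescaled x must be positive",
                             class = "radiorobust_validation_error")
  g <- family_transform(family, xr)
  with_rr_seed(seed, {
    alpha <- stats::runif(n_regions, alpha_range[1], alpha_range[2])
    beta <- stats::runif(n_regions, beta_range[1], beta_range[2])
    vals <- outer(g, alpha) + rep(beta, each = length(x))
    if (sigma > 0) vals <- vals + stats::rnorm(length(vals), sd = sigma)
    out <- data.frame(
      feature = feature,
      family = "synthetic",
      region = rep(paste0("region", seq_len(n_regions)), each = length(x)),
      group = group,
      x_value = rep(x, n_regions),
      value = as.vector(vals),
      valid = TRUE,
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- list(family = family, alpha = alpha, beta = beta)
    out
  })
}
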