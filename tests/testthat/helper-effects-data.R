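# Synthetic generator for attribution tests: per-region covariates and a
# response with chosen fixed-effect weights plus per-region random structure.
make_effects_data <- function(seed, n_regions = 9, n_levels = 11,
                              w_par = 1, w_vol = 0, w_int = 0,
                              noise = 0.3) {
  set.seed(seed)
  x <- seq_len(n_levels)
  regions <- paste0("r", seq_len(n_regions))
  base_vol <- rlnorm(n_regions, 8, 1)
  base_int <- runif(n_regions, 2, 20)
  cov <- do.call(rbind, lapply(seq_len(n_regions), function(i) {
    data.frame(region = regions[i], x_value = x,
               mesh_volume = base_vol[i] * (1 + 0.02 * x + rnorm(n_levels, sd = 0.01)),
               mean_intensity = base_int[i] * (1 - 0.01 * x + rnorm(n_levels, sd = 0.01)))
  }))
  b0 <- rnorm(n_regions, sd = 0.5)
  b1 <- rnorm(n_regions, sd = 0.1)
  vals <- do.call(rbind, lapply(seq_len(n_regions), function(i) {
    ci <- cov[cov$region == regions[i], ]
    zv <- (ci$mesh_volume - mean(cov$mesh_volume)) / sd(cov$mesh_volume)
    zi <- (ci$mean_intensity - mean(cov$mean_intensity)) / sd(cov$mean_intensity)
    zx <- (x - mean(x)) / sd(x)
    data.frame(region = regions[i], x_value = x,
               value = w_par * zx + w_vol * zv + w_int * zi +
                 b0[i] + b1[i] * zx + rnorm(n_levels, sd = noise))
  }))
  list(values = vals, covariates = cov)
}
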