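# Small, fast phantom configurations for the property tests. Tumor sizes
# are scaled down (14-20 mm at 1 mm isotropic spacing) so a case fits in
# a ~25^3 grid; the study-calibrated defaults are exercised separately
# via the geometry fast path.

quick_params <- function(label = "UTUC", size = 16, mean_hu = 50,
                         noise_sd = 12, corr = 2, necrosis = 0) {
  phantom_class_params(label, size_median_mm = size, size_log_sd = 0.15,
                       axis_ratio_range = c(0.6, 0.85),
                       mean_hu = mean_hu, noise_sd_hu = noise_sd,
                       texture_corr_mm = corr, necrosis_prob = necrosis)
}

quick_case <- function(seed = 1, ...) {
  p <- quick_params(...)
  tv <- generate_tumor_volume(p, spacing_mm = c(1, 1, 1), seed = seed)
  lesion_case(paste0("q", seed), tv$volume, tv$mask, label = p$label,
              geometry = tv$geometry)
}

# Two-class test cohort config; identical classes unless a contrast is
# requested via the rcc_* arguments.
two_class_config <- function(n, seed, utuc_hu = 50, rcc_hu = 50,
                             noise_sd = 12, utuc_size = 15,
                             rcc_size = 15, jitter = 0.8) {
  stopifnot(n %% 2 == 0)
  params <- list(
    "ccRCC" = phantom_class_params(
      "RCC", size_median_mm = rcc_size, size_log_sd = 0.15,
      axis_ratio_range = c(0.6, 0.85), mean_hu = rcc_hu,
      noise_sd_hu = noise_sd, texture_corr_mm = 2),
    "high-grade UTUC" = phantom_class_params(
      "UTUC", size_median_mm = utuc_size, size_log_sd = 0.15,
      axis_ratio_range = c(0.6, 0.85), mean_hu = utuc_hu,
      noise_sd_hu = noise_sd, texture_corr_mm = 2))
  cohort_config(n_cases = n,
                class_counts = c("ccRCC" = n / 2,
                                 "high-grade UTUC" = n / 2),
                class_params = params, voxel_spacing_mm = c(1, 1, 1),
                reader_jitter_mm = jitter, seed = seed)
}
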