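# shared fixtures built in code

wildtype_params <- function(...) {
  args <- utils::modifyList(
    list(name = "wildtype", tcc_intercept = 8, tcc_slope_volume = 16,
         cellcount_beta0 = 352.0, cellcount_beta1 = 7261.3,
         v0 = 0.1, noise_sd_tcc = 1, noise_sd_cells = 530),
    list(...)
  )
  do.call(genotype_params, args)
}

# exact (tcc, volume) pairs on a known line
linear_tcc_df <- function(slope = 16, intercept = 8, n = 10) {
  v <- seq(0.1, 1.0, length.out = n)
  tibble::tibble(volume_nl = v, tcc_hr = intercept + slope * v)
}

# small noise-free gradient scene shared across profile tests
ds_scene <- function(semiaxes = c(150, 120), ...) {
  gen_gradient_image(gradient_scene_params(
    semiaxes = semiaxes, profile_kind = "ds_like_border_high", ...
  ))
}

# one extracted + normalized AP profile for a given pouch size
normalized_ap_profile <- function(a_um, scaling_mode, seed,
                                  noise_sd = 560, pixel_size = 0.5) {
  p <- gradient_scene_params(semiaxes = c(a_um, 0.8 * a_um),
                             scaling_mode = scaling_mode,
                             noise_sd = noise_sd, seed = seed,
                             pixel_size = pixel_size)
  sc <- gen_gradient_image(p)
  prof <- extract_profile(sc$image, sc$midline_ap, mask = sc$mask)
  normalize_axis(prof, c(-a_um, a_um))
}
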