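#' Parameters for a synthetic gradient scene
#'
#' Describes an elliptical wing pouch carrying a radial intensity gradient,
#' used to emulate Fat-GFP / Ds-GFP expression patterns. The intensity
#' inside the pouch is a quadratic function of the normalized elliptical
#' radius rho (0 at the centre, 1 at the border):
#'
#' * `ds_like_border_high`: low at the centre (`min_level`), rising to
#'   `max_level` at the border;
#' * `fat_like_center_high`: high at the centre, falling to `min_level` at
#'   the border.
#'
#' The anterior half (negative AP offsets) has its amplitude reduced by up
#' to `anterior_asymmetry` at the anterior border, emulating the asymmetric
#' Ds gradient. `scaling_mode` controls how the profile behaves across
#' pouch sizes: `axis_scaling` keeps the profile a fixed function of
#' normalized position (profiles collapse after axis normalization), while
#' `max_decay` multiplies the amplitude by `decay_reference_um /
#' semiaxes[1]`, so the peak diminishes as the pouch grows (profiles fail
#' to collapse).
#'
#' @param semiaxes Length-2 numeric, AP and DV semiaxes in um.
#' @param pixel_size Pixel size in um/px (default 0.25).
#' @param image_shape Optional `c(ny, nx)` in pixels; default fits the
#'   ellipse with a 60-px margin.
#' @param center Optional `c(x_px, y_px)` centre; default image centre.
#' @param profile_kind `"ds_like_border_high"` or `"fat_like_center_high"`.
#' @param min_level,max_level Intensity limits (arbitrary units,
#'   `min_level < max_level`).
#' @param anterior_asymmetry Fractional amplitude reduction at the anterior
#'   border, in \[0, 1\].
#' @param scaling_mode `"axis_scaling"` or `"max_decay"`.
#' @param decay_reference_um Reference AP semiaxis at which the `max_decay`
#'   amplitude factor is 1.
#' @param noise_sd Gaussian noise SD added to every pixel.
#' @param seed Integer seed for the noise.
#' @return A `gradient_scene_params` list.
#' @export
gradient_scene_params <- function(semiaxes = c(100, 80), pixel_size = 0.25,
                                  image_shape = NULL, center = NULL,
                                  profile_kind = c("ds_like_border_high",
                                                   "fat_like_center_high"),
                                  min_level = 2000, max_level = 30000,
                                  anterior_asymmetry = 0,
                                  scaling_mode = c("axis_scaling", "max_decay"),
                                  decay_reference_um = 100,
                                  noise_sd = 0, seed = 1L) {
  profile_kind <- match.arg(profile_kind)
  scaling_mode <- match.arg(scaling_mode)
  if (min_level >= max_level) {
    stop("gradient_scene_params(): min_level must be below max_level", call. = FALSE)
  }
  if (anterior_asymmetry < 0 || anterior_asymmetry > 1) {
    stop("gradient_scene_params(): anterior_asymmetry must lie in [0, 1]",
         call. = FALSE)
  }
  stopifnot(length(semiaxes) == 2, all(semiaxes > 0), pixel_size > 0,
            noise_sd >= 0)
  a_px <- ceiling(semiaxes[1] / pixel_size)
  b_px <- ceiling(semiaxes[2] / pixel_size)
  if (is.null(image_shape)) {
    image_shape <- c(2 * b_px + 120, 2 * a_px + 120)
  }
  if (is.null(center)) {
    center <- c(ceiling(image_shape[2] / 2), ceiling(image_shape[1] / 2))
  }
  if (center[1] - a_px < 1 || center[1] + a_px > image_shape[2] ||
      center[2] - b_px < 1 || center[2] + b_px > image_shape[1]) {
    stop("gradient_scene_params(): ellipse does not fit inside the image",
         call. = FALSE)
  }
  structure(
    list(semiaxes = semiaxes, pixel_size = pixel_size,
         image_shape = as.integer(image_shape), center = center,
         profile_kind = profile_kind, min_level = min_level,
         max_level = max_level, anterior_asymmetry = anterior_asymmetry,
         scaling_mode = scaling_mode, decay_reference_um = decay_reference_um,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "gradient_scene_params"
  )
}

#' Render a synthetic gradient image with midlines and pouch mask
#'
#' Builds the intensity image described by [gradient_scene_params()], the
#' AP and DV midline polylines through the pouch centre (1-px steps along
#' the semiaxes, centre point at arc position 0), and the elliptical pouch
#' mask. Pixels outside the mask hold background (0) plus noise.
#'
#' @param p A [gradient_scene_params()].
#' @return A `gradient_scene` list: `image` (matrix, rows = y),
#'   `midline_ap`, `midline_dv` ([midline()] objects), `mask` (logical
#'   matrix), and `params`.
#' @export
gen_gradient_image <- function(p) {
  stopifnot(inherits(p, "gradient_scene_params"))
  ny <- p$image_shape[1]
  nx <- p$image_shape[2]
  a <- p$semiaxes[1]
  b <- p$semiaxes[2]
  dx <- (matrix(seq_len(nx), ny, nx, byrow = TRUE) - p$center[1]) * p$pixel_size
  dy <- (matrix(seq_len(ny), ny, nx) - p$center[2]) * p$pixel_size
  rho2 <- (dx / a)^2 + (dy / b)^2
  mask <- rho2 <= 1
  shape <- if (p$profile_kind == "ds_like_border_high") rho2 else 1 - rho2
  asym <- 1 - p$anterior_asymmetry * pmax(0, -dx / a)
  decay <- if (p$scaling_mode == "max_decay") p$decay_reference_um / a else 1
  image <- matrix(0, ny, nx)
  image[mask] <- p$min_level +
    (p$max_level - p$min_level) * (decay * asym * shape)[mask]
  if (p$noise_sd > 0) {
    image <- image + withr::with_seed(p$seed,
                                      matrix(stats::rnorm(ny * nx, 0, p$noise_sd), ny, nx))
  }
  a_px <- floor(a / p$pixel_size)
  b_px <- floor(b / p$pixel_size)
  midline_ap <- midline(
    x_px = seq(p$center[1] - a_px, p$center[1] + a_px),
    y_px = rep(p$center[2], 2 * a_px + 1),
    pixel_size = p$pixel_size, center_index = a_px + 1
  )
  midline_dv <- midline(
    x_px = rep(p$center[1], 2 * b_px + 1),
    y_px = seq(p$center[2] - b_px, p$center[2] + b_px),
    pixel_size = p$pixel_size, center_index = b_px + 1
  )
  structure(
    list(image = image, midline_ap = midline_ap, midline_dv = midline_dv,
         mask = mask, params = p),
    class = "gradient_scene"
  )
}

#' Analytic intensity of a gradient scene at given AP offsets
#'
#' The noise-free generating function along the AP midline, used as an
#' oracle for profile extraction: intensity at signed AP offset `x_um` from
#' the centre (negative anterior).
#'
#' @param p A [gradient_scene_params()].
#' @param x_um Signed AP offsets in um.
#' @return Numeric intensities.
#' @export
scene_ap_intensity <- function(p, x_um) {
  stopifnot(inherits(p, "gradient_scene_params"))
  rho2 <- (x_um / p$semiaxes[1])^2
  shape <- if (p$profile_kind == "ds_like_border_high") rho2 else 1 - rho2
  asym <- 1 - p$anterior_asymmetry * pmax(0, -x_um / p$semiaxes[1])
  decay <- if (p$scaling_mode == "max_decay") {
    p$decay_reference_um / p$semiaxes[1]
  } else 1
  ifelse(rho2 <= 1,
         p$min_level + (p$max_level - p$min_level) * decay * asym * shape,
         0)
}
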