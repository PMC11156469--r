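#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot scaling_fit
#' @export
autoplot.scaling_fit <- function(object, ...) {
  data <- object$model$model
  band <- predict_band(object)
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[object$regressor]],
                                     y = .data[[object$response]])) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$at, ymin = .data$lwr,
                                      ymax = .data$upr),
                         inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(x = .data$at, y = .data$fit),
                       inherit.aes = FALSE) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = if (object$regressor == "volume_nl") "Wing pouch volume (nL)" else "Larval age (hr)",
      y = "Average cell cycle time (hr)",
      title = sprintf("Scaling coefficient: %.2f hr/nL (95%% CI %.2f-%.2f)",
                      object$slope, object$ci95_slope[1], object$ci95_slope[2])
    )
}

#' @method autoplot time_fit
#' @export
autoplot.time_fit <- autoplot.scaling_fit

#' @method autoplot trajectory
#' @export
autoplot.trajectory <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_hr,
                                            y = .data$volume_nl))
  if ("lo95" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95,
                                               ymax = .data$hi95),
                                  alpha = 0.2)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "Larval age (hr)", y = "Wing pouch volume (nL)",
                  title = "Simulated pouch growth")
}

#' @method autoplot intensity_profile
#' @export
autoplot.intensity_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                            y = .data$mean_intensity))
  if (any(is.finite(object$sem))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_intensity - .data$sem,
                   ymax = .data$mean_intensity + .data$sem),
      alpha = 0.2
    )
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(
      x = if (isTRUE(attr(object, "normalized"))) "Normalized axis position"
          else "Position (µm)",
      y = "Mean intensity (a.u.)"
    )
}

#' Overlay a family of intensity profiles
#'
#' @param profiles Named or unnamed list of `intensity_profile`s.
#' @return A ggplot.
#' @export
plot_profile_family <- function(profiles) {
  labels <- names(profiles) %||% paste0("profile_", seq_along(profiles))
  data <- purrr::map2_dfr(profiles, labels, function(p, lab) {
    tibble::tibble(position = p$position, mean_intensity = p$mean_intensity,
                   profile = lab)
  })
  ggplot2::ggplot(data, ggplot2::aes(x = .data$position,
                                     y = .data$mean_intensity,
                                     colour = .data$profile)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Axis position", y = "Mean intensity (a.u.)")
}

#' @method autoplot allometry_fit
#' @export
autoplot.allometry_fit <- function(object, ...) {
  mf <- object$model$model
  x <- mf$x
  grid <- seq(min(x), max(x), length.out = 100)
  pred <- if (object$two_phase) {
    object$intercept + object$phase1_slope * grid +
      (object$phase2_slope - object$phase1_slope) * pmax(grid - object$breakpoint, 0)
  } else {
    object$intercept + object$phase1_slope * grid
  }
  ggplot2::ggplot(tibble::tibble(x = x, y = mf[[1]]),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = tibble::tibble(x = grid, y = pred)) +
    ggplot2::labs(x = "log10 body weight (mg)", y = "log10 pouch volume (nL)",
                  title = "Two-phase allometric growth")
}
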