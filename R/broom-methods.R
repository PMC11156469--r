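#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy cellcount_model
#' @export
tidy.cellcount_model <- function(x, ...) {
  tibble::tibble(
    term = c("beta0", "beta1"),
    estimate = c(x$beta0, x$beta1),
    std.error = c(x$se_beta0, x$se_beta1)
  )
}

#' @method glance cellcount_model
#' @export
glance.cellcount_model <- function(x, ...) {
  tibble::tibble(genotype = x$genotype, r.squared = x$r_squared,
                 p.value = x$p_value, nobs = x$n)
}

#' @method tidy slope_fit
#' @export
tidy.slope_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", x$regressor),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope)
  )
}

#' @method glance slope_fit
#' @export
glance.slope_fit <- function(x, ...) {
  tibble::tibble(genotype = x$genotype, slope = x$slope,
                 se.slope = x$se_slope, conf.low = x$ci95_slope[1],
                 conf.high = x$ci95_slope[2], r.squared = x$r_squared,
                 p.value = x$p_slope, nobs = x$n)
}

#' @method tidy interaction_fit
#' @export
tidy.interaction_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("beta0", "beta1_volume", "beta2_genotype", "beta3_interaction"),
    estimate = c(x$beta0, x$beta1_volume, x$beta2_genotype, x$beta3_interaction),
    std.error = c(x$se_beta0, x$se_beta1, x$se_beta2, x$se_beta3),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @method glance interaction_fit
#' @export
glance.interaction_fit <- function(x, ...) {
  tibble::tibble(reference = x$labels[1], comparison = x$labels[2],
                 slope.reference = x$beta1_volume,
                 slope.comparison = x$beta1_volume + x$beta3_interaction,
                 slope.difference = x$beta3_interaction,
                 p.interaction = x$p_interaction, nobs = x$n)
}

#' @method tidy allometry_fit
#' @export
tidy.allometry_fit <- function(x, ...) {
  tibble::tibble(
    term = c("phase1_slope", "phase2_slope", "breakpoint"),
    estimate = c(x$phase1_slope, x$phase2_slope, x$breakpoint),
    std.error = c(x$se_phase1, x$se_phase2, NA_real_)
  )
}

#' @method glance allometry_fit
#' @export
glance.allometry_fit <- function(x, ...) {
  tibble::tibble(
    two.phase = x$two_phase,
    phase1.slope = x$phase1_slope, phase2.slope = x$phase2_slope,
    breakpoint = x$breakpoint,
    phase1.class = unname(x$classification["phase1"]),
    phase2.class = if (x$two_phase) unname(x$classification["phase2"]) else NA_character_,
    sse = x$sse, nobs = x$n
  )
}

#' @export
print.cellcount_model <- function(x, ...) {
  cat("Cell-number conversion model", if (!is.na(x$genotype)) paste0("(", x$genotype, ")"), "\n")
  cat(sprintf("  total_cells = %.1f + %.1f x volume_nl\n", x$beta0, x$beta1))
  cat(sprintf("  R^2 = %.3f, slope p = %.3g, n = %d\n", x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("Cell-cycle scaling fit", if (!is.na(x$genotype)) paste0("(", x$genotype, ")"), "\n")
  cat(sprintf("  scaling coefficient: %.3f hr/nL (SE %.3f, 95%% CI %.3f-%.3f)\n",
              x$slope, x$se_slope, x$ci95_slope[1], x$ci95_slope[2]))
  cat(sprintf("  intercept: %.3f hr; R^2 = %.3f; n = %d\n",
              x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @export
print.time_fit <- function(x, ...) {
  cat("Cell-cycle vs age fit", if (!is.na(x$genotype)) paste0("(", x$genotype, ")"), "\n")
  cat(sprintf("  Tcc = %.3f + %.4f x age (hr); slope SE %.4f; n = %d\n",
              x$t0, x$beta1_time, x$se_beta1, x$n))
  invisible(x)
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("Scaling-coefficient comparison:", x$labels[1], "vs", x$labels[2], "\n")
  cat(sprintf("  slope difference (beta3): %.3f hr/nL (SE %.3f), p = %.3g\n",
              x$beta3_interaction, x$se_beta3, x$p_interaction))
  invisible(x)
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat("Log-log allometry fit\n")
  if (x$two_phase) {
    cat(sprintf("  phase 1 slope: %.3f (%s)\n", x$phase1_slope,
                x$classification["phase1"]))
    cat(sprintf("  phase 2 slope: %.3f (%s)\n", x$phase2_slope,
                x$classification["phase2"]))
    cat(sprintf("  breakpoint: %.3f log10 mg (%.3f mg)\n", x$breakpoint,
                10^x$breakpoint))
  } else {
    cat(sprintf("  slope: %.3f (%s)\n", x$phase1_slope,
                x$classification["phase1"]))
  }
  invisible(x)
}
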