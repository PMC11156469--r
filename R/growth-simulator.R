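#' Growth-simulation configuration
#'
#' @param v0 Initial pouch volume in nL.
#' @param t_start,t_end Simulated span of larval age in hours.
#' @param dt Time step in hours; the default 1 hr reproduces the discrete
#'   recursion `V_t = (1 + r_t) * V_(t-1)` exactly, other steps use the
#'   first-order generalization `V_t = (1 + r_t * dt) * V_(t-dt)`.
#' @param tm M-phase transit time in hours; cell-cycle times at or below
#'   `tm` are unphysical and rejected.
#' @param n_draws Monte-Carlo draws for uncertainty propagation.
#' @param seed Integer seed for uncertainty propagation.
#' @return A `growth_config` list.
#' @export
growth_config <- function(v0, t_start = 0, t_end = 36, dt = 1, tm = 0.34,
                          n_draws = 500, seed = 1L) {
  stopifnot(v0 > 0, dt > 0, t_end > t_start, tm > 0, n_draws >= 1)
  structure(list(v0 = v0, t_start = t_start, t_end = t_end, dt = dt, tm = tm,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "growth_config")
}

#' Simulate a wing-pouch volume trajectory from fitted kinetics
#'
#' Iterates the discrete growth recursion `V_t = (1 + r_t * dt) * V_(t-dt)`
#' from `v0`, with the instantaneous rate `r_t = ln(2) / (T0 + beta1 * t)`
#' taken from a linear fit of cell-cycle time on larval age.
#'
#' @param fit A `time_fit` from [fit_tcc_vs_time()], or any list with
#'   elements `t0` and `beta1_time`.
#' @param config A [growth_config()].
#' @return A `trajectory` tibble with columns `time_hr`, `volume_nl`.
#' @export
simulate_trajectory <- function(fit, config) {
  stopifnot(inherits(config, "growth_config"))
  t0 <- fit$t0
  b1 <- fit$beta1_time
  times <- seq(config$t_start, config$t_end, by = config$dt)
  tcc <- t0 + b1 * times
  if (any(tcc <= config$tm)) {
    stop("simulate_trajectory(): cell-cycle time falls to or below the ",
         "M-phase duration inside the simulated span", call. = FALSE)
  }
  volumes <- numeric(length(times))
  volumes[1] <- config$v0
  r <- log(2) / tcc
  for (k in seq_along(times)[-1]) {
    volumes[k] <- (1 + r[k] * config$dt) * volumes[k - 1]
  }
  new_trajectory(times, volumes, fit = fit, config = config)
}

new_trajectory <- function(times, volumes, lo = NULL, hi = NULL, fit, config) {
  out <- tibble::tibble(time_hr = times, volume_nl = volumes)
  if (!is.null(lo)) {
    out$lo95 <- lo
    out$hi95 <- hi
  }
  structure(out, fit = fit[c("t0", "beta1_time", "se_beta1")],
            config = config, class = c("trajectory", class(out)))
}

#' Propagate slope uncertainty onto the growth trajectory
#'
#' Draws cell-cycle-vs-age slope values from a normal distribution centred
#' on the fitted slope with SD equal to its standard error, simulates a
#' trajectory for each draw, and reports the pointwise 2.5/97.5 percentile
#' envelope around the central trajectory. Draws that push the cell-cycle
#' time to or below the M-phase duration anywhere in the span are rejected;
#' more than 20% rejections is an error (the fit is then too uncertain to
#' propagate meaningfully).
#'
#' @param fit A `time_fit` carrying `se_beta1`.
#' @param config A [growth_config()]; `n_draws` must be at least 100.
#' @return A `trajectory` tibble with `lo95` and `hi95` band columns.
#' @export
propagate_uncertainty <- function(fit, config) {
  stopifnot(inherits(config, "growth_config"))
  if (is.null(fit$se_beta1) || is.na(fit$se_beta1)) {
    stop("propagate_uncertainty(): fit must carry se_beta1", call. = FALSE)
  }
  if (config$n_draws < 100) {
    stop("propagate_uncertainty(): need at least 100 draws", call. = FALSE)
  }
  central <- simulate_trajectory(fit, config)
  times <- central$time_hr
  draws <- withr::with_seed(config$seed,
                            stats::rnorm(config$n_draws, fit$beta1_time, fit$se_beta1))
  # a draw is physical iff Tcc stays above tm at both ends of the span
  tcc_ends <- outer(c(config$t_start, config$t_end), draws) + fit$t0
  ok <- tcc_ends[1, ] > config$tm & tcc_ends[2, ] > config$tm
  n_rej <- sum(!ok)
  if (n_rej > 0) {
    message("propagate_uncertainty(): rejected ", n_rej, " unphysical draw(s)")
  }
  if (n_rej > 0.2 * config$n_draws) {
    stop("propagate_uncertainty(): more than 20% of slope draws produce ",
         "unphysical cell-cycle times", call. = FALSE)
  }
  draws <- draws[ok]
  # volume matrix: rows = time steps, columns = draws
  r <- log(2) / (fit$t0 + outer(times, draws))
  vol <- matrix(config$v0, nrow = length(times), ncol = length(draws))
  for (k in seq_along(times)[-1]) {
    vol[k, ] <- (1 + r[k, ] * config$dt) * vol[k - 1, ]
  }
  lo <- apply(vol, 1, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(vol, 1, stats::quantile, probs = 0.975, names = FALSE)
  new_trajectory(times, central$volume_nl,
                 lo = pmin(lo, central$volume_nl),
                 hi = pmax(hi, central$volume_nl),
                 fit = fit, config = config)
}

#' Compare a simulated trajectory to observed pouch volumes
#'
#' Observed volumes are averaged per timepoint and matched to the nearest
#' simulated time (within half a step); residuals, the RMSE of the
#' timepoint means, and the fraction of means inside the 95% band (when
#' present) are reported.
#'
#' @param traj A `trajectory`.
#' @param records Data frame of observed pouches with `age_hr` and
#'   `volume_nl`.
#' @return A `growth_gof` list with a per-timepoint tibble (`by_time`),
#'   `rmse` and `band_coverage`.
#' @export
compare_to_observed <- function(traj, records) {
  require_columns(records, c("age_hr", "volume_nl"), "compare_to_observed")
  obs <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(records), .data$age_hr),
    observed_nl = mean(.data$volume_nl), n = dplyr::n(), .groups = "drop"
  )
  dt <- attr(traj, "config")$dt
  idx <- vapply(obs$age_hr, function(a) {
    j <- which.min(abs(traj$time_hr - a))
    if (abs(traj$time_hr[j] - a) <= dt / 2) j else NA_integer_
  }, integer(1))
  keep <- !is.na(idx)
  if (!any(keep)) {
    stop("compare_to_observed(): no observed timepoints overlap the trajectory",
         call. = FALSE)
  }
  obs <- obs[keep, ]
  idx <- idx[keep]
  by_time <- dplyr::mutate(
    obs,
    simulated_nl = traj$volume_nl[idx],
    residual_nl = .data$observed_nl - .data$simulated_nl
  )
  coverage <- NA_real_
  if ("lo95" %in% names(traj)) {
    inside <- by_time$observed_nl >= traj$lo95[idx] &
      by_time$observed_nl <= traj$hi95[idx]
    coverage <- mean(inside)
    by_time$in_band <- inside
  }
  structure(
    list(by_time = by_time,
         rmse = sqrt(mean(by_time$residual_nl^2)),
         band_coverage = coverage),
    class = "growth_gof"
  )
}

#' @export
print.growth_gof <- function(x, ...) {
  cat("Growth-model goodness of fit\n")
  cat("  timepoints compared:", nrow(x$by_time), "\n")
  cat("  RMSE of timepoint means:", signif(x$rmse, 4), "nL\n")
  if (!is.na(x$band_coverage)) {
    cat("  fraction of means inside 95% band:", signif(x$band_coverage, 3), "\n")
  }
  invisible(x)
}
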