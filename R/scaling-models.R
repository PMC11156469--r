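#' Fit cell-cycle time against pouch volume (scaling coefficient)
#'
#' Ordinary least squares of average cell-cycle time on wing-pouch volume.
#' The fitted slope, in hours per nanolitre, is the *scaling coefficient*:
#' how much the cell cycle lengthens per nL of pouch growth.
#'
#' @param data Data frame with columns `tcc_hr` and `volume_nl`; rows with
#'   missing cell-cycle times are dropped.
#' @param genotype Optional label stored with the fit.
#' @return A `scaling_fit` with `slope`, `intercept`, standard errors,
#'   `r_squared`, `p_slope`, `ci95_slope` and `n`.
#' @export
fit_tcc_vs_volume <- function(data, genotype = NULL) {
  require_columns(data, c("tcc_hr", "volume_nl"), "fit_tcc_vs_volume")
  new_slope_fit(data, response = "tcc_hr", regressor = "volume_nl",
                genotype = genotype, class = "scaling_fit")
}

#' Fit cell-cycle time against larval age
#'
#' Ordinary least squares of average cell-cycle time on larval age,
#' `tcc = T0 + beta1 * t`, where `T0` is the cell-cycle time at t = 0.
#' The slope standard error is carried into growth-simulation uncertainty
#' propagation.
#'
#' @param data Data frame with columns `tcc_hr` and `age_hr`.
#' @param genotype Optional label stored with the fit.
#' @return A `time_fit` with `t0`, `beta1_time`, `se_t0`, `se_beta1`, `n`.
#' @export
fit_tcc_vs_time <- function(data, genotype = NULL) {
  require_columns(data, c("tcc_hr", "age_hr"), "fit_tcc_vs_time")
  fit <- new_slope_fit(data, response = "tcc_hr", regressor = "age_hr",
                       genotype = genotype, class = "time_fit")
  fit$t0 <- fit$intercept
  fit$beta1_time <- fit$slope
  fit$se_t0 <- fit$se_intercept
  fit$se_beta1 <- fit$se_slope
  fit
}

# shared simple-OLS machinery for the two slope fits
new_slope_fit <- function(data, response, regressor, genotype, class) {
  data <- tibble::as_tibble(data)
  data <- data[is.finite(data[[response]]) & is.finite(data[[regressor]]), ]
  if (nrow(data) < 3) {
    stop(class, ": need at least 3 complete observations", call. = FALSE)
  }
  if (length(unique(data[[regressor]])) < 2) {
    stop(class, ": degenerate design, regressor has no spread", call. = FALSE)
  }
  if (is.null(genotype) && "genotype" %in% names(data)) {
    genotype <- as.character(unique(data$genotype))[1]
  }
  fml <- stats::reformulate(regressor, response)
  fit <- stats::lm(fml, data = data)
  sm <- quiet_summary(fit)
  ci <- quiet_perfect_fit(stats::confint(fit, level = 0.95))
  structure(
    list(
      genotype     = genotype %||% NA_character_,
      slope        = unname(stats::coef(fit)[2]),
      intercept    = unname(stats::coef(fit)[1]),
      se_slope     = sm$coefficients[2, "Std. Error"],
      se_intercept = sm$coefficients[1, "Std. Error"],
      r_squared    = sm$r.squared,
      p_slope      = sm$coefficients[2, "Pr(>|t|)"],
      ci95_slope   = unname(ci[2, ]),
      n            = nrow(data),
      regressor    = regressor,
      response     = response,
      model        = fit
    ),
    class = c(class, "slope_fit")
  )
}

#' Predicted values with 95% confidence bands
#'
#' @param fit A `scaling_fit` or `time_fit`.
#' @param at Regressor values (volumes in nL, or ages in hr) at which to
#'   evaluate the fit; defaults to the observed range.
#' @return Tibble with columns `at`, `fit`, `lwr`, `upr`.
#' @export
predict_band <- function(fit, at = NULL) {
  stopifnot(inherits(fit, "slope_fit"))
  if (is.null(at)) {
    rng <- range(fit$model$model[[fit$regressor]])
    at <- seq(rng[1], rng[2], length.out = 50)
  }
  newdata <- stats::setNames(data.frame(at), fit$regressor)
  pr <- stats::predict(fit$model, newdata = newdata,
                       interval = "confidence", level = 0.95)
  tibble::tibble(at = at, fit = pr[, "fit"], lwr = pr[, "lwr"], upr = pr[, "upr"])
}

#' Compare scaling coefficients between genotypes
#'
#' Pools a reference and a comparison dataset and fits the multiple
#' regression `tcc = beta0 + beta1*volume + beta2*genotype +
#' beta3*volume*genotype` with the genotype dummy coded 0 for the reference
#' and 1 for the comparison group. `beta3` is the difference in scaling
#' coefficient; its two-sided t-test p-value tests whether the slopes differ.
#'
#' @param reference,comparison Data frames with `tcc_hr` and `volume_nl`.
#' @param labels Length-2 character vector naming the two groups.
#' @return An `interaction_fit` with coefficients `beta0`..`beta3`, their
#'   standard errors, and `p_interaction`.
#' @export
compare_scaling <- function(reference, comparison,
                            labels = c("reference", "comparison")) {
  require_columns(reference, c("tcc_hr", "volume_nl"), "compare_scaling")
  require_columns(comparison, c("tcc_hr", "volume_nl"), "compare_scaling")
  ref <- tibble::as_tibble(reference)[c("tcc_hr", "volume_nl")]
  cmp <- tibble::as_tibble(comparison)[c("tcc_hr", "volume_nl")]
  ref <- ref[stats::complete.cases(ref), ]
  cmp <- cmp[stats::complete.cases(cmp), ]
  if (nrow(ref) < 3 || nrow(cmp) < 3) {
    stop("compare_scaling(): each group needs at least 3 complete observations",
         call. = FALSE)
  }
  pooled <- dplyr::bind_rows(
    dplyr::mutate(ref, g = 0),
    dplyr::mutate(cmp, g = 1)
  )
  fit <- stats::lm(tcc_hr ~ volume_nl * g, data = pooled)
  sm <- quiet_summary(fit)$coefficients
  structure(
    list(
      labels            = labels,
      beta0             = unname(stats::coef(fit)["(Intercept)"]),
      beta1_volume      = unname(stats::coef(fit)["volume_nl"]),
      beta2_genotype    = unname(stats::coef(fit)["g"]),
      beta3_interaction = unname(stats::coef(fit)["volume_nl:g"]),
      se_beta0          = sm["(Intercept)", "Std. Error"],
      se_beta1          = sm["volume_nl", "Std. Error"],
      se_beta2          = sm["g", "Std. Error"],
      se_beta3          = sm["volume_nl:g", "Std. Error"],
      p_interaction     = sm["volume_nl:g", "Pr(>|t|)"],
      p_genotype        = sm["g", "Pr(>|t|)"],
      n                 = nrow(pooled),
      model             = fit
    ),
    class = "interaction_fit"
  )
}

#' Two-phase log-log allometry fit
#'
#' Fits organ size against body size on log10-log10 axes. With
#' `two_phase = TRUE` the model is continuous piecewise-linear with a hinge
#' (breakpoint) in log body size; if the breakpoint is not supplied it is
#' estimated by profiled grid search over interior data quantiles,
#' minimizing the residual sum of squares. Each phase's slope is classified
#' against 1 by a two-sided t-test at alpha = 0.05: isometric when 1 is not
#' rejected, positive/negative allometry when the slope is significantly
#' above/below 1.
#'
#' @param data Data frame with columns `body_weight_mg` and
#'   `pouch_volume_nl`.
#' @param breakpoint Optional fixed breakpoint on the log10 body-weight
#'   scale (e.g. the weight at feeding cessation); must lie inside the data
#'   range.
#' @param two_phase Fit a hinge model (default) or a single line.
#' @return An `allometry_fit` with per-phase slopes, intercepts, standard
#'   errors, the breakpoint, and per-phase classifications.
#' @export
fit_allometry <- function(data, breakpoint = NULL, two_phase = TRUE) {
  require_columns(data, c("body_weight_mg", "pouch_volume_nl"), "fit_allometry")
  data <- tibble::as_tibble(data)
  data <- data[stats::complete.cases(data[c("body_weight_mg", "pouch_volume_nl")]), ]
  if (any(data$body_weight_mg <= 0) || any(data$pouch_volume_nl <= 0)) {
    stop("fit_allometry(): sizes must be positive for log transformation",
         call. = FALSE)
  }
  x <- log10(data$body_weight_mg)
  y <- log10(data$pouch_volume_nl)
  if (length(x) < (if (two_phase) 6 else 3)) {
    stop("fit_allometry(): too few observations", call. = FALSE)
  }
  if (!two_phase) {
    fit <- stats::lm(y ~ x)
    sm <- quiet_summary(fit)$coefficients
    return(structure(
      list(
        two_phase = FALSE,
        phase1_slope = unname(stats::coef(fit)[2]),
        phase2_slope = NA_real_,
        intercept = unname(stats::coef(fit)[1]),
        breakpoint = NA_real_,
        se_phase1 = sm[2, "Std. Error"],
        se_phase2 = NA_real_,
        classification = c(phase1 = classify_slope(
          stats::coef(fit)[2], sm[2, "Std. Error"], stats::df.residual(fit))),
        sse = sum(stats::residuals(fit)^2),
        n = length(x),
        model = fit
      ),
      class = "allometry_fit"
    ))
  }
  if (is.null(breakpoint)) {
    # profiled grid search over interior quantiles of log body weight
    grid <- unique(stats::quantile(x, probs = seq(0.1, 0.9, length.out = 60),
                                   names = FALSE))
    sse <- vapply(grid, function(b) hinge_sse(x, y, b), numeric(1))
    k <- which.min(sse)
    # refine between the neighbouring grid points
    lo <- grid[max(k - 1, 1)]
    hi <- grid[min(k + 1, length(grid))]
    breakpoint <- if (lo < hi) {
      stats::optimize(function(b) hinge_sse(x, y, b), c(lo, hi),
                      tol = 1e-8)$minimum
    } else grid[k]
  } else if (breakpoint <= min(x) || breakpoint >= max(x)) {
    stop("fit_allometry(): breakpoint outside the data range", call. = FALSE)
  }
  hinge <- pmax(x - breakpoint, 0)
  fit <- stats::lm(y ~ x + hinge)
  co <- stats::coef(fit)
  vc <- quiet_perfect_fit(stats::vcov(fit))
  se1 <- sqrt(vc["x", "x"])
  se2 <- sqrt(vc["x", "x"] + vc["hinge", "hinge"] + 2 * vc["x", "hinge"])
  df <- stats::df.residual(fit)
  structure(
    list(
      two_phase = TRUE,
      phase1_slope = unname(co["x"]),
      phase2_slope = unname(co["x"] + co["hinge"]),
      intercept = unname(co["(Intercept)"]),
      breakpoint = breakpoint,
      se_phase1 = se1,
      se_phase2 = se2,
      classification = c(
        phase1 = classify_slope(co["x"], se1, df),
        phase2 = classify_slope(co["x"] + co["hinge"], se2, df)
      ),
      sse = sum(stats::residuals(fit)^2),
      n = length(x),
      model = fit
    ),
    class = "allometry_fit"
  )
}

hinge_sse <- function(x, y, b) {
  h <- pmax(x - b, 0)
  sum(stats::resid(stats::lm(y ~ x + h))^2)
}

# slope-vs-1 t-test at alpha = 0.05; slopes within numerical precision of 1
# (exact-fit degenerate case) are isometric by convention
classify_slope <- function(slope, se, df) {
  if (abs(slope - 1) < 1e-8) {
    p <- 1
  } else if (se == 0) {
    p <- 0
  } else {
    p <- 2 * stats::pt(abs((slope - 1) / se), df = df, lower.tail = FALSE)
  }
  if (p >= 0.05) "isometric"
  else if (slope > 1) "positive_allometry"
  else "negative_allometry"
}

# lm helpers warn about "essentially perfect fit" on noise-free inputs,
# which are a legitimate degenerate case for this package's oracles
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(
    expr,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

quiet_summary <- function(fit) quiet_perfect_fit(summary(fit))
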