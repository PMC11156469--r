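test_that("scaling fit is exact on linear data and invariant to row order", {
  d <- linear_tcc_df(slope = 16, intercept = 8)
  f <- fit_tcc_vs_volume(d)
  expect_equal(f$slope, 16, tolerance = 1e-10)
  expect_equal(f$intercept, 8, tolerance = 1e-10)
  expect_equal(f$r_squared, 1)
  # confidence band computable at arbitrary volumes
  band <- predict_band(f, at = c(0.2, 0.6))
  expect_true(all(band$lwr <= band$fit & band$fit <= band$upr))
  # permutation invariance
  noisy <- gen_scaling_dataset(wildtype_params(), seed = 8)
  f1 <- fit_tcc_vs_volume(noisy)
  f2 <- fit_tcc_vs_volume(noisy[sample(nrow(noisy)), ])
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f1$se_slope, f2$se_slope, tolerance = 1e-12)
  # unit equivariance: volumes in pL scale the slope by 1e-3
  pl <- dplyr::mutate(noisy, volume_nl = volume_nl * 1e3)
  expect_equal(fit_tcc_vs_volume(pl)$slope, f1$slope / 1e3, tolerance = 1e-12)
  expect_error(fit_tcc_vs_volume(noisy[1:2, ]), "at least 3")
})

test_that("time fit recovers generating intercept and slope", {
  ages <- rep(seq(0, 36, by = 4), 4)
  exact <- tibble::tibble(age_hr = ages, tcc_hr = 10 + 0.5 * ages)
  f <- fit_tcc_vs_time(exact)
  expect_equal(f$t0, 10, tolerance = 1e-10)
  expect_equal(f$beta1_time, 0.5, tolerance = 1e-10)
  # stochastic recovery: estimates fall within 3 SE almost always,
  # and a flat generator is not mistaken for a trend
  hits <- vapply(1:200, function(s) {
    tcc <- withr::with_seed(s, 10 + 0.5 * ages + stats::rnorm(length(ages)))
    ft <- fit_tcc_vs_time(tibble::tibble(age_hr = ages, tcc_hr = tcc))
    abs(ft$beta1_time - 0.5) < 3 * ft$se_beta1
  }, logical(1))
  expect_gte(mean(hits), 0.97)
  flat <- vapply(1:100, function(s) {
    tcc <- withr::with_seed(s, rep(12, length(ages)) + stats::rnorm(length(ages)))
    ft <- fit_tcc_vs_time(tibble::tibble(age_hr = ages, tcc_hr = tcc))
    abs(ft$beta1_time) < 2 * ft$se_beta1
  }, logical(1))
  expect_gte(mean(flat), 0.9)
})

test_that("interaction model reproduces marginal slopes and the null case", {
  a <- gen_scaling_dataset(wildtype_params(), n = 30, seed = 41)
  b <- gen_scaling_dataset(wildtype_params(), n = 30, seed = 42)
  cmp <- compare_scaling(a, b)
  # reference slope equals the single-group fit on the reference data
  expect_equal(cmp$beta1_volume, fit_tcc_vs_volume(a)$slope, tolerance = 1e-12)
  # comparison group's marginal slope is beta1 + beta3
  expect_equal(cmp$beta1_volume + cmp$beta3_interaction,
               fit_tcc_vs_volume(b)$slope, tolerance = 1e-10)
  # identical groups: interaction indistinguishable from zero
  self <- compare_scaling(a, a)
  expect_lt(abs(self$beta3_interaction), 2 * self$se_beta3 + 1e-12)
  expect_equal(self$beta1_volume, fit_tcc_vs_volume(a)$slope, tolerance = 1e-12)
  expect_error(compare_scaling(a[1:2, ], b), "at least 3")
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_equal(nrow(tidy(cmp)), 4)
})

test_that("interaction test separates a halved scaling coefficient", {
  p <- vapply(1:50, function(s) {
    a <- gen_scaling_dataset(wildtype_params(), n = 30, seed = s)
    b <- gen_scaling_dataset(genotype_presets()$ds_rnai, n = 30,
                             seed = s + 5000)
    compare_scaling(a, b)$p_interaction
  }, numeric(1))
  expect_gte(mean(p < 0.01), 0.95)
})

test_that("allometry fitting handles single lines, hinges, and errors", {
  w <- seq(0.5, 2, length.out = 30)
  iso <- tibble::tibble(body_weight_mg = w, pouch_volume_nl = 0.3 * w)
  f1 <- fit_allometry(iso, two_phase = FALSE)
  expect_equal(f1$phase1_slope, 1, tolerance = 1e-10)
  expect_equal(unname(f1$classification["phase1"]), "isometric")
  # single-line fit agrees with plain OLS on the logs
  ols <- stats::lm(log10(pouch_volume_nl) ~ log10(body_weight_mg), data = iso)
  expect_equal(f1$phase1_slope, unname(stats::coef(ols)[2]), tolerance = 1e-12)
  # supplied breakpoint must be interior
  d <- gen_allometry_series(1.0, 2.5, 1.2, n = 40, noise_sd = 0.02, seed = 6)
  expect_error(fit_allometry(d, breakpoint = 2), "range")
  ff <- fit_allometry(d, breakpoint = log10(1.2))
  expect_equal(ff$breakpoint, log10(1.2))
  expect_lt(abs(ff$phase1_slope - 1.0), 3 * ff$se_phase1)
  expect_lt(abs(ff$phase2_slope - 2.5), 3 * ff$se_phase2)
  expect_equal(unname(ff$classification["phase2"]), "positive_allometry")
  expect_error(fit_allometry(d[1:4, ]), "too few")
  expect_error(
    fit_allometry(tibble::tibble(body_weight_mg = c(1, -1, 1, 1, 1, 1),
                                 pouch_volume_nl = rep(1, 6))),
    "positive"
  )
})

test_that("tidy and glance summaries expose the fitted coefficients", {
  d <- gen_scaling_dataset(wildtype_params(), seed = 14)
  f <- fit_tcc_vs_volume(d)
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "volume_nl"], f$slope)
  gl <- glance(f)
  expect_true(gl$conf.low <= f$slope && f$slope <= gl$conf.high)
  m <- fit_cellcount_model(gen_cellcount_dataset(wildtype_params(), seed = 14))
  expect_equal(tidy(m)$term, c("beta0", "beta1"))
  expect_true(glance(m)$r.squared <= 1)
  af <- fit_allometry(gen_allometry_series(1, 2.5, 1.2, seed = 2))
  expect_equal(nrow(tidy(af)), 3)
  expect_equal(glance(af)$two.phase, TRUE)
})
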