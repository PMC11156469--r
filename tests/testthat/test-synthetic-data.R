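test_that("genotype parameter validation enforces one cell-cycle law", {
  expect_error(genotype_params("x"), "law")
  expect_error(genotype_params("x", tcc_slope_volume = 16), "tcc_intercept")
  expect_error(genotype_params("x", tcc_t0 = 10), "tcc_slope_time")
  expect_error(wildtype_params(v0 = -1), "v0")
  expect_error(wildtype_params(noise_sd_tcc = -1), "noise")
  expect_equal(wildtype_params()$law, "volume")
  expect_equal(genotype_params("t", tcc_t0 = 10, tcc_slope_time = 0.5)$law,
               "time")
})

test_that("pouch growth generator is deterministic and obeys its recursion", {
  gp <- wildtype_params()
  a <- gen_pouch_growth(gp, seed = 11)
  b <- gen_pouch_growth(gp, seed = 11)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_false(identical(a$volume_nl, gen_pouch_growth(gp, seed = 12)$volume_nl))
  # zero noise + constant cell-cycle time: exact exponential closed form
  const <- genotype_params("const", tcc_t0 = 10, tcc_slope_time = 0,
                           v0 = 0.1)
  recs <- gen_pouch_growth(const, ages = 0:20, n_per_age = 1, seed = 1,
                           volume_jitter_sdlog = 0)
  expect_equal(recs$volume_nl, 0.1 * (1 + log(2) / 10)^(0:20),
               tolerance = 1e-10)
  # derived geometry reproduces the stored volume through pouch_volume
  vols <- pouch_volume(gen_pouch_growth(gp, seed = 2))
  expect_equal(vols$volume_nl,
               gen_pouch_growth(gp, seed = 2)$volume_nl, tolerance = 1e-9)
})

test_that("regression on generator output recovers the generating scaling slope", {
  gp <- wildtype_params()
  recs <- gen_pouch_growth(gp, ages = seq(0, 36, by = 4), n_per_age = 5,
                           seed = 21)
  # hidden truths lie exactly on the volume law
  expect_equal(recs$tcc_true_hr, 8 + 16 * recs$volume_nl, tolerance = 1e-12)
  fit <- stats::lm(tcc_true_hr ~ volume_nl, data = recs)
  se <- suppressWarnings(summary(fit))$coefficients[2, 2]
  expect_lt(abs(stats::coef(fit)[2] - 16), 2 * se + 1e-8)
})

test_that("unphysical cell-cycle parameters are rejected", {
  shrink <- genotype_params("bad", tcc_t0 = 1, tcc_slope_time = -0.5, v0 = 0.1)
  expect_error(gen_pouch_growth(shrink, ages = seq(0, 10)), "unphysical|M-phase")
})

test_that("mitotic count generation matches its binomial sampling model", {
  gp <- wildtype_params(noise_sd_cells = 0)
  # constant true Tcc = 100 * tm so MI = 0.01; pool many large pouches
  recs <- tibble::tibble(pouch_id = sprintf("p%03d", 1:200),
                         volume_nl = 1, tcc_true_hr = 0.34 * 100)
  mit <- gen_mitotic_counts(recs, tm = 0.34, params = gp, seed = 5)
  n_tot <- sum(mit$total_cells_true)
  mi_hat <- sum(mit$phh3_count) / n_tot
  se <- sqrt(0.01 * 0.99 / n_tot)
  expect_lt(abs(mi_hat - 0.01), 3 * se)
  # noise-free cell counts reproduce the Table-style conversion: 352 + 7261.3
  expect_true(all(mit$total_cells_true == 7613L))
  # subdomain density is consistent with the total count
  est <- estimate_total_cells(mit)
  expect_lt(max(abs(est$total_cells - mit$total_cells_true) /
                  mit$total_cells_true), 0.15)
  # empty input, empty output
  empty <- gen_mitotic_counts(recs[0, ], params = gp, seed = 1)
  expect_equal(nrow(empty), 0)
  # M phase longer than the cycle is impossible
  bad <- tibble::tibble(pouch_id = "p", volume_nl = 1, tcc_true_hr = 0.2)
  expect_error(gen_mitotic_counts(bad, tm = 0.34, params = gp, seed = 1),
               "exceed")
})

test_that("allometry series generator obeys its piecewise-linear law", {
  # noise-free: points lie exactly on the hinge; fit recovers it exactly
  d0 <- gen_allometry_series(1.0, 2.5, 1.2, n = 60, noise_sd = 0, seed = 3)
  expect_equal(log10(d0$pouch_volume_nl), d0$log10_volume_true,
               tolerance = 1e-12)
  f0 <- fit_allometry(d0)
  expect_equal(f0$phase1_slope, 1.0, tolerance = 1e-4)
  expect_equal(f0$phase2_slope, 2.5, tolerance = 1e-4)
  expect_equal(10^f0$breakpoint, 1.2, tolerance = 1e-3)
  # equal slopes: the hinge adds essentially nothing over a single line
  de <- gen_allometry_series(1.5, 1.5, 1.2, n = 60, noise_sd = 0, seed = 4)
  expect_lt(fit_allometry(de)$sse, 1e-10)
  expect_error(gen_allometry_series(1, 2, break_weight = 10, n = 20, seed = 1),
               "range")
  expect_error(gen_allometry_series(-1, 2, 1.2), "positive")
  expect_identical(gen_allometry_series(1, 2.5, 1.2, seed = 9),
                   gen_allometry_series(1, 2.5, 1.2, seed = 9))
})

test_that("gradient scenes are deterministic and noise-free values are exact", {
  p <- gradient_scene_params(semiaxes = c(100, 80), anterior_asymmetry = 0.3)
  sc <- gen_gradient_image(p)
  sc2 <- gen_gradient_image(p)
  expect_identical(serialize(sc$image, NULL), serialize(sc2$image, NULL))
  cx <- p$center[1]; cy <- p$center[2]
  # ds-like: centre at min_level, posterior border at max_level,
  # anterior border scaled down by the asymmetry
  expect_equal(sc$image[cy, cx], p$min_level)
  a_px <- 100 / p$pixel_size
  expect_equal(sc$image[cy, cx + a_px], p$max_level)
  expect_equal(sc$image[cy, cx - a_px],
               p$min_level + (p$max_level - p$min_level) * (1 - 0.3))
  # background holds baseline only
  expect_equal(sc$image[5, 5], 0)
  # midlines pass through the centre
  expect_equal(sc$midline_ap$y_px[1], cy)
  ap_pos <- arc_positions(sc$midline_ap)
  expect_equal(ap_pos[attr(sc$midline_ap, "center_index")], 0)
})

test_that("scene parameter validation rejects impossible geometry", {
  expect_error(gradient_scene_params(min_level = 10, max_level = 5), "min_level")
  expect_error(gradient_scene_params(anterior_asymmetry = 1.5), "asymmetry")
  expect_error(gradient_scene_params(semiaxes = c(500, 80),
                                     image_shape = c(100, 100)),
               "fit inside")
})
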