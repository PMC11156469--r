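test_that("arc positions respect curvature and the centre convention", {
  # straight 3-point line, 10 px spacing at 1 um/px, centre in the middle
  line <- midline(c(0, 10, 20), c(5, 5, 5), pixel_size = 1, center_index = 2)
  expect_equal(arc_positions(line), c(-10, 0, 10))
  # right angle: cumulative arc, not the chord
  bent <- midline(c(0, 10, 10), c(0, 0, 10), pixel_size = 1, center_index = 1)
  expect_equal(arc_positions(bent), c(0, 10, 20))
  # reversing the point order negates each physical point's position
  rev_line <- midline(c(20, 10, 0), c(5, 5, 5), pixel_size = 1, center_index = 2)
  expect_equal(arc_positions(rev_line), -rev(arc_positions(line)))
  expect_error(midline(c(0, 0), c(1, 1), 1, 1), "distinct")
  expect_error(midline(c(0, 1), c(0, 1), 1, 5), "center_index")
})

test_that("profile extraction reproduces flat and separable fields", {
  img <- matrix(7.5, nrow = 60, ncol = 120)
  line <- midline(10:110, rep(30, 101), pixel_size = 0.5, center_index = 51)
  prof <- extract_profile(img, line, profile_params(orthogonal_halfwidth = 10,
                                                    window_length = 20))
  expect_true(all(abs(prof$mean_intensity - 7.5) < 1e-12))
  # intensity varying only orthogonally, symmetric about the line:
  # transect averaging cancels and the profile equals the on-line values
  sym <- outer(seq_len(60), seq_len(120),
               function(y, x) 100 + (y - 30)^2)
  prof_sym <- extract_profile(sym, line,
                              profile_params(orthogonal_halfwidth = 5,
                                             window_length = 1))
  on_line <- 100 + mean(((-5):5)^2)
  expect_true(all(abs(prof_sym$mean_intensity - on_line) < 1e-9))
})

test_that("noise-free synthetic scenes are recovered within 1% of range", {
  p <- gradient_scene_params(semiaxes = c(150, 120), anterior_asymmetry = 0.2)
  sc <- gen_gradient_image(p)
  prof <- extract_profile(sc$image, sc$midline_ap, mask = sc$mask)
  truth <- scene_ap_intensity(p, prof$position)
  rel <- abs(prof$mean_intensity - truth) / (p$max_level - p$min_level)
  expect_lt(max(rel), 0.01)
})

test_that("extraction is equivariant under joint image/polyline translation", {
  p <- gradient_scene_params(semiaxes = c(60, 50), pixel_size = 0.5)
  sc <- gen_gradient_image(p)
  shift <- c(7L, -5L)  # (x, y)
  ny <- nrow(sc$image); nx <- ncol(sc$image)
  big <- matrix(0, ny + 20, nx + 20)
  big[1:ny + 10 + shift[2], 1:nx + 10 + shift[1]] <- sc$image
  moved <- midline(sc$midline_ap$x_px + 10 + shift[1],
                   sc$midline_ap$y_px + 10 + shift[2],
                   pixel_size = attr(sc$midline_ap, "pixel_size"),
                   center_index = attr(sc$midline_ap, "center_index"))
  p_orig <- extract_profile(sc$image, sc$midline_ap)
  p_moved <- extract_profile(big, moved)
  expect_equal(p_moved$mean_intensity, p_orig$mean_intensity, tolerance = 1e-12)
  expect_equal(p_moved$position, p_orig$position)
})

test_that("alignment and averaging pool profiles pointwise", {
  base <- ds_scene(semiaxes = c(80, 60), pixel_size = 0.5)
  prof <- extract_profile(base$image, base$midline_ap, mask = base$mask)
  avg <- align_and_average(list(prof, prof, prof))
  common <- avg$position
  expect_equal(avg$mean_intensity,
               stats::approx(prof$position, prof$mean_intensity, common)$y,
               tolerance = 1e-10)
  expect_true(all(avg$sem < 1e-10))
  expect_equal(attr(avg, "n_discs"), 3L)
  # two flat profiles at 0 and 2: mean 1, SEM 1 everywhere
  flat <- function(v) {
    structure(tibble::tibble(position = -10:10, mean_intensity = v,
                             sem = NA_real_),
              n_discs = 1L, normalized = FALSE,
              class = c("intensity_profile", class(tibble::tibble())))
  }
  two <- align_and_average(list(flat(0), flat(2)))
  expect_true(all(abs(two$mean_intensity - 1) < 1e-12))
  expect_true(all(abs(two$sem - 1) < 1e-12))
  # grid-shifted copies of a smooth profile average back to the original
  shifted <- lapply(c(0, 0.3, 0.6), function(dx) {
    structure(tibble::tibble(position = seq(-20, 20, 0.5) + dx,
                             mean_intensity = sin((seq(-20, 20, 0.5) + dx) / 5),
                             sem = NA_real_),
              n_discs = 1L, normalized = FALSE,
              class = c("intensity_profile", class(tibble::tibble())))
  })
  pooled <- align_and_average(shifted)
  expect_equal(pooled$mean_intensity, sin(pooled$position / 5),
               tolerance = 0.02)
  expect_error(align_and_average(list(flat(0))), "at least 2")
  far <- flat(0); far$position <- far$position + 100
  expect_error(align_and_average(list(flat(0), far)), "overlap")
})

test_that("axis normalization maps extents to +/-0.5 and round-trips", {
  prof <- structure(
    tibble::tibble(position = seq(-100, 100, 10),
                   mean_intensity = seq(-100, 100, 10)^2, sem = NA_real_),
    n_discs = 1L, normalized = FALSE,
    class = c("intensity_profile", class(tibble::tibble()))
  )
  norm <- normalize_axis(prof, c(-100, 100))
  expect_equal(range(norm$position), c(-0.5, 0.5))
  expect_equal(norm$mean_intensity, prof$mean_intensity)
  back <- denormalize_axis(norm)
  expect_equal(back$position, prof$position, tolerance = 1e-12)
  expect_error(normalize_axis(prof, c(-50, 100)), "bracket")
  expect_error(normalize_axis(norm, c(-1, 1)), "already")
})

test_that("geometrically similar scenes collapse after normalization", {
  profs <- lapply(c(100, 150, 200), function(a) {
    normalized_ap_profile(a, "axis_scaling", seed = 61, noise_sd = 0)
  })
  grid <- seq(-0.45, 0.45, length.out = 50)
  vals <- sapply(profs, function(p) {
    stats::approx(p$position, p$mean_intensity, grid)$y
  })
  spread <- apply(vals, 1, function(r) diff(range(r)))
  expect_lt(max(spread) / (30000 - 2000), 0.03)
})

test_that("collapse verdicts separate scaling modes and ignore affine gain", {
  collapsing <- lapply(c(100, 150, 200), function(a) {
    normalized_ap_profile(a, "axis_scaling", seed = 71)
  })
  cs <- collapse_score(collapsing)
  expect_lt(cs$score, 0.1)
  expect_equal(cs$verdict, "collapsed")
  decaying <- lapply(c(100, 150, 200), function(a) {
    normalized_ap_profile(a, "max_decay", seed = 72)
  })
  cd <- collapse_score(decaying)
  expect_gt(cd$score, 0.1)
  expect_equal(cd$verdict, "not_collapsed")
  # common affine rescaling of intensities leaves the score unchanged
  rescaled <- lapply(collapsing, function(p) {
    p$mean_intensity <- 3 * p$mean_intensity + 500
    p
  })
  expect_equal(collapse_score(rescaled)$score, cs$score, tolerance = 1e-10)
  # identical profiles: score 0
  expect_equal(collapse_score(list(collapsing[[1]], collapsing[[1]]))$score, 0)
  # degenerate constant family warns
  flatp <- collapsing[[1]]; flatp$mean_intensity <- rep(1, nrow(flatp))
  expect_warning(collapse_score(list(flatp, flatp)), "constant")
  expect_error(collapse_score(list(collapsing[[1]],
                                   denormalize_axis(collapsing[[2]],
                                                    c(-150, 150)))),
               "normalized")
})

test_that("profile extrema report positions with centre-ward tie breaking", {
  mono <- structure(
    tibble::tibble(position = 0:10, mean_intensity = 0:10, sem = NA_real_),
    n_discs = 1L, normalized = FALSE,
    class = c("intensity_profile", class(tibble::tibble()))
  )
  ex <- profile_extrema(mono)
  expect_equal(ex$argmin, 0)
  expect_equal(ex$argmax, 10)
  u <- structure(
    tibble::tibble(position = -5:5, mean_intensity = (-5:5)^2, sem = NA_real_),
    n_discs = 1L, normalized = FALSE,
    class = c("intensity_profile", class(tibble::tibble()))
  )
  expect_equal(profile_extrema(u)$argmin, 0)
  # amplitude-decaying families have strictly decreasing maxima with size
  maxima <- vapply(c(100, 150, 200), function(a) {
    profile_extrema(normalized_ap_profile(a, "max_decay", seed = 81,
                                          noise_sd = 0))$max
  }, numeric(1))
  expect_true(all(diff(maxima) < 0))
})

test_that("averaging suppresses pixel noise in extracted profiles", {
  sd_noise <- 800
  p0 <- gradient_scene_params(semiaxes = c(80, 64), pixel_size = 0.5,
                              noise_sd = 0)
  pn <- gradient_scene_params(semiaxes = c(80, 64), pixel_size = 0.5,
                              noise_sd = sd_noise, seed = 91)
  clean <- extract_profile(gen_gradient_image(p0)$image,
                           gen_gradient_image(p0)$midline_ap)
  noisy <- extract_profile(gen_gradient_image(pn)$image,
                           gen_gradient_image(pn)$midline_ap)
  # the moving window and transect average ~ window * transect samples
  bound <- 3 * sd_noise / sqrt(100 * 51)
  expect_lt(max(abs(noisy$mean_intensity - clean$mean_intensity)), 3 * bound)
})
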