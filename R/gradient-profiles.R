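#' Midline polyline
#'
#' An ordered polyline of pixel coordinates tracing a pouch midline (AP or
#' DV), with the pixel size and the index of the point at the AP/DV
#' intersection (the pouch centre, arc position 0).
#'
#' @param x_px,y_px Ordered pixel coordinates (anterior/dorsal end first).
#' @param pixel_size Pixel size in um/px.
#' @param center_index Index of the centre point on the polyline.
#' @return A `midline` tibble with `x_px`, `y_px` columns.
#' @export
midline <- function(x_px, y_px, pixel_size, center_index) {
  if (length(x_px) < 2 || length(x_px) != length(y_px)) {
    stop("midline(): need at least 2 paired points", call. = FALSE)
  }
  if (any(diff(x_px) == 0 & diff(y_px) == 0)) {
    stop("midline(): consecutive points must be distinct", call. = FALSE)
  }
  if (center_index < 1 || center_index > length(x_px)) {
    stop("midline(): center_index must lie on the polyline", call. = FALSE)
  }
  structure(tibble::tibble(x_px = x_px, y_px = y_px),
            pixel_size = pixel_size, center_index = as.integer(center_index),
            class = c("midline", class(tibble::tibble())))
}

#' Signed arc-length positions along a midline
#'
#' Cumulative Euclidean distance along the polyline (so curvature is
#' respected, not chord distance), converted to um and signed about the
#' centre point: anterior/dorsal positions are negative, posterior/ventral
#' positive.
#'
#' @param line A [midline()].
#' @return Numeric vector of positions in um, one per polyline point.
#' @export
arc_positions <- function(line) {
  stopifnot(inherits(line, "midline"))
  d <- cumsum(c(0, sqrt(diff(line$x_px)^2 + diff(line$y_px)^2)))
  (d - d[attr(line, "center_index")]) * attr(line, "pixel_size")
}

#' Profile-extraction parameters
#'
#' Window sizes are in pixels, matching how they are defined on the
#' acquisition scale; they are deliberately not rescaled by the pixel size,
#' so images at a very different resolution need adjusted windows.
#'
#' @param orthogonal_halfwidth Pixels averaged on each side of the midline
#'   (default 25, i.e. a 50-px transect plus the centre pixel's row).
#' @param window_length Sliding-window length in pixels along the arc
#'   (default 100).
#' @param sample_step Arc sampling step in polyline points (default 1).
#' @return A `profile_params` list.
#' @export
profile_params <- function(orthogonal_halfwidth = 25, window_length = 100,
                           sample_step = 1) {
  stopifnot(orthogonal_halfwidth > 0, window_length > 0, sample_step >= 1)
  structure(list(orthogonal_halfwidth = as.integer(orthogonal_halfwidth),
                 window_length = as.integer(window_length),
                 sample_step = as.integer(sample_step)),
            class = "profile_params")
}

new_profile <- function(position, mean_intensity, sem, n_discs, normalized) {
  structure(
    tibble::tibble(position = position, mean_intensity = mean_intensity,
                   sem = sem),
    n_discs = n_discs, normalized = normalized,
    class = c("intensity_profile", class(tibble::tibble()))
  )
}

#' Extract an intensity profile along a midline
#'
#' At each sampled point of the midline, intensity is averaged across a
#' transect orthogonal to the local tangent (nearest-pixel sampling,
#' `orthogonal_halfwidth` pixels each side, clipped to the image and to the
#' pouch mask when given). The transect means are then smoothed with a
#' centred moving average of `window_length` pixels sliding along the arc
#' (shrinking at the ends). The local tangent is estimated from polyline
#' neighbours two points away on each side.
#'
#' @param image Numeric matrix (rows = y, columns = x).
#' @param line A [midline()].
#' @param params A [profile_params()].
#' @param mask Optional logical matrix of the same shape; transect samples
#'   outside the mask are ignored.
#' @return An `intensity_profile` tibble (`position` in um,
#'   `mean_intensity`, `sem` = NA for a single disc).
#' @export
extract_profile <- function(image, line, params = profile_params(), mask = NULL) {
  stopifnot(inherits(line, "midline"), is.matrix(image))
  n <- nrow(line)
  idx <- seq(1, n, by = params$sample_step)
  # local tangent over +/- 2 polyline points, clamped at the ends
  i_lo <- pmax(idx - 2L, 1L)
  i_hi <- pmin(idx + 2L, n)
  tx <- line$x_px[i_hi] - line$x_px[i_lo]
  ty <- line$y_px[i_hi] - line$y_px[i_lo]
  tl <- sqrt(tx^2 + ty^2)
  nx <- -ty / tl
  ny <- tx / tl
  h <- params$orthogonal_halfwidth
  offsets <- -h:h
  # sample coordinates: rows = arc samples, cols = transect offsets
  sx <- round(matrix(line$x_px[idx], length(idx), length(offsets)) + outer(nx, offsets))
  sy <- round(matrix(line$y_px[idx], length(idx), length(offsets)) + outer(ny, offsets))
  valid <- sx >= 1 & sx <= ncol(image) & sy >= 1 & sy <= nrow(image)
  vals <- matrix(NA_real_, nrow = length(idx), ncol = length(offsets))
  lin <- (sx[valid] - 1) * nrow(image) + sy[valid]
  vals[valid] <- image[lin]
  if (!is.null(mask)) {
    vv <- vals[valid]
    vv[!mask[lin]] <- NA_real_
    vals[valid] <- vv
  }
  transect_mean <- rowMeans(vals, na.rm = TRUE)
  keep <- is.finite(transect_mean)
  if (!all(keep)) {
    warning("extract_profile(): dropped ", sum(!keep),
            " position(s) with no in-bounds transect samples", call. = FALSE)
  }
  if (!any(keep)) {
    stop("extract_profile(): every transect fell outside the image/mask",
         call. = FALSE)
  }
  pos <- arc_positions(line)[idx][keep]
  w_samp <- max(1L, as.integer(round(params$window_length / params$sample_step)))
  smoothed <- partial_moving_mean(transect_mean[keep], w_samp)
  new_profile(pos, smoothed, sem = rep(NA_real_, sum(keep)),
              n_discs = 1L, normalized = FALSE)
}

# centred moving mean; windows shrink symmetrically at the ends so the
# average stays centred on its sample (no inward bias at the profile edges)
partial_moving_mean <- function(x, window) {
  n <- length(x)
  half <- window %/% 2
  i <- seq_len(n)
  h <- pmin(half, i - 1L, n - i)
  cs <- cumsum(c(0, x))
  (cs[i + h + 1] - cs[i - h]) / (2 * h + 1)
}

#' Align profiles at their centres and average across discs
#'
#' Profiles are interpolated onto a common position grid covering the
#' intersection of their supports (positions outside any profile's support
#' are excluded), then averaged pointwise; the SEM across discs (n-1
#' denominator) is reported.
#'
#' @param profiles List of `intensity_profile`s on the same position scale
#'   (all raw um, or all axis-normalized).
#' @return An `intensity_profile` with `n_discs` equal to the total.
#' @export
align_and_average <- function(profiles) {
  if (length(profiles) < 2) {
    stop("align_and_average(): need at least 2 profiles", call. = FALSE)
  }
  norm_flags <- vapply(profiles, function(p) attr(p, "normalized"), logical(1))
  if (length(unique(norm_flags)) > 1) {
    stop("align_and_average(): cannot mix raw and normalized profiles",
         call. = FALSE)
  }
  lo <- max(vapply(profiles, function(p) min(p$position), numeric(1)))
  hi <- min(vapply(profiles, function(p) max(p$position), numeric(1)))
  if (lo >= hi) {
    stop("align_and_average(): profile supports do not overlap", call. = FALSE)
  }
  npts <- as.integer(round(stats::median(vapply(profiles, nrow, numeric(1)))))
  grid <- seq(lo, hi, length.out = max(npts, 2))
  mat <- vapply(profiles, function(p) {
    stats::approx(p$position, p$mean_intensity, xout = grid)$y
  }, numeric(length(grid)))
  new_profile(
    grid,
    rowMeans(mat),
    sem = apply(mat, 1, stats::sd) / sqrt(ncol(mat)),
    n_discs = sum(vapply(profiles, function(p) attr(p, "n_discs"), integer(1))),
    normalized = norm_flags[1]
  )
}

#' Rescale profile positions to a normalized axis
#'
#' Maps arc positions to the interval \[-0.5, 0.5\] relative to the axis
#' extent, preserving 0 at the centre (each side is scaled by its own
#' half-axis length, so asymmetric axes keep their centre at 0). Intensities
#' are untouched.
#'
#' @param profile An `intensity_profile` in um.
#' @param axis_extent Length-2 numeric: the axis limits in um
#'   (negative anterior/dorsal extent, positive posterior/ventral extent);
#'   must bracket the profile's positions.
#' @return The profile with normalized positions (`normalized` flag set).
#' @export
normalize_axis <- function(profile, axis_extent) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (isTRUE(attr(profile, "normalized"))) {
    stop("normalize_axis(): profile is already normalized", call. = FALSE)
  }
  ext <- sort(axis_extent)
  if (ext[1] >= 0 || ext[2] <= 0) {
    stop("normalize_axis(): axis_extent must span negative and positive sides",
         call. = FALSE)
  }
  if (min(profile$position) < ext[1] || max(profile$position) > ext[2]) {
    stop("normalize_axis(): axis_extent does not bracket the profile",
         call. = FALSE)
  }
  pos <- ifelse(profile$position < 0,
                0.5 * profile$position / abs(ext[1]),
                0.5 * profile$position / ext[2])
  out <- new_profile(pos, profile$mean_intensity, profile$sem,
                     attr(profile, "n_discs"), normalized = TRUE)
  attr(out, "axis_extent") <- ext
  out
}

#' Undo axis normalization
#'
#' @param profile A normalized `intensity_profile` (carrying its
#'   `axis_extent`, or supplied explicitly).
#' @param axis_extent Optional length-2 extent in um.
#' @return The profile back on the um scale.
#' @export
denormalize_axis <- function(profile, axis_extent = NULL) {
  stopifnot(inherits(profile, "intensity_profile"))
  if (!isTRUE(attr(profile, "normalized"))) {
    stop("denormalize_axis(): profile is not normalized", call. = FALSE)
  }
  ext <- axis_extent %||% attr(profile, "axis_extent")
  if (is.null(ext)) {
    stop("denormalize_axis(): no axis_extent available", call. = FALSE)
  }
  ext <- sort(ext)
  pos <- ifelse(profile$position < 0,
                profile$position * abs(ext[1]) / 0.5,
                profile$position * ext[2] / 0.5)
  new_profile(pos, profile$mean_intensity, profile$sem,
              attr(profile, "n_discs"), normalized = FALSE)
}

#' Collapse score for a family of normalized profiles
#'
#' Quantifies whether axis-normalized profiles from pouches of different
#' sizes superimpose ("collapse", the signature of a gradient that scales
#' with tissue size). Profiles are resampled onto a common grid over their
#' shared support; the score is the mean pairwise RMS difference divided by
#' the family's pooled dynamic range. The verdict is "collapsed" when the
#' score is below `threshold` (default 0.1 of the dynamic range; the
#' threshold is reported alongside every verdict).
#'
#' @param profiles List of >= 2 normalized `intensity_profile`s.
#' @param threshold Collapse threshold as a fraction of the dynamic range.
#' @return A `collapse_verdict` list: `score`, `verdict`, `threshold`,
#'   `n_profiles`, `dynamic_range`.
#' @export
collapse_score <- function(profiles, threshold = 0.1) {
  if (length(profiles) < 2) {
    stop("collapse_score(): need at least 2 profiles", call. = FALSE)
  }
  if (!all(vapply(profiles, function(p) isTRUE(attr(p, "normalized")), logical(1)))) {
    stop("collapse_score(): profiles must be axis-normalized first", call. = FALSE)
  }
  lo <- max(vapply(profiles, function(p) min(p$position), numeric(1)))
  hi <- min(vapply(profiles, function(p) max(p$position), numeric(1)))
  if (lo >= hi) {
    stop("collapse_score(): profile supports do not overlap", call. = FALSE)
  }
  grid <- seq(lo, hi, length.out = 101)
  mat <- vapply(profiles, function(p) {
    stats::approx(p$position, p$mean_intensity, xout = grid)$y
  }, numeric(length(grid)))
  rng <- max(mat) - min(mat)
  if (rng == 0) {
    warning("collapse_score(): constant profile family; score is 0", call. = FALSE)
    score <- 0
  } else {
    pairs <- utils::combn(ncol(mat), 2)
    rms <- apply(pairs, 2, function(ij) {
      sqrt(mean((mat[, ij[1]] - mat[, ij[2]])^2))
    })
    score <- mean(rms) / rng
  }
  structure(
    list(score = score,
         verdict = if (score < threshold) "collapsed" else "not_collapsed",
         threshold = threshold,
         n_profiles = length(profiles),
         dynamic_range = rng),
    class = "collapse_verdict"
  )
}

#' @export
print.collapse_verdict <- function(x, ...) {
  cat("Gradient collapse score:", signif(x$score, 4),
      sprintf("(threshold %.3g) -> %s across %d profiles\n",
              x$threshold, x$verdict, x$n_profiles))
  invisible(x)
}

#' Profile extrema
#'
#' Extreme mean intensities of a profile and their arc positions. Ties are
#' broken toward the centre (smallest absolute position), so a symmetric
#' U-shaped profile reports its minimum at 0.
#'
#' @param profile An `intensity_profile`.
#' @return One-row tibble: `min`, `max`, `argmin`, `argmax`.
#' @export
profile_extrema <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"), nrow(profile) > 0)
  m <- profile$mean_intensity
  pick <- function(cand) cand[which.min(abs(profile$position[cand]))]
  i_min <- pick(which(m == min(m)))
  i_max <- pick(which(m == max(m)))
  tibble::tibble(min = m[i_min], max = m[i_max],
                 argmin = profile$position[i_min],
                 argmax = profile$position[i_max])
}
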