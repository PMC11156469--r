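#' Genotype parameters for the synthetic-data generators
#'
#' Collects the generating parameters for one genotype: a law for the
#' average cell-cycle time, the linear cell-number-vs-volume conversion, the
#' initial pouch volume, and noise magnitudes. Exactly one cell-cycle law is
#' used per genotype:
#'
#' * **volume law** `tcc = tcc_intercept + tcc_slope_volume * V` (the
#'   scaling-coefficient relationship), used when `tcc_slope_volume` is
#'   supplied;
#' * **time law** `tcc = tcc_t0 + tcc_slope_time * t`, used otherwise.
#'
#' @param name Genotype label.
#' @param tcc_intercept Cell-cycle time (hr) at zero volume (volume law).
#' @param tcc_slope_volume Scaling coefficient, hr per nL (volume law).
#' @param tcc_t0 Cell-cycle time (hr) at age 0 (time law).
#' @param tcc_slope_time Cell-cycle lengthening rate, hr per hr (time law).
#' @param cellcount_beta0,cellcount_beta1 Cell-number conversion
#'   coefficients (cells, cells per nL).
#' @param v0 Initial pouch volume in nL.
#' @param noise_sd_tcc SD of Gaussian noise on observed cell-cycle times, hr.
#' @param noise_sd_cells SD of Gaussian noise on generated cell counts.
#' @return A `genotype_params` list.
#' @export
genotype_params <- function(name,
                            tcc_intercept = NULL, tcc_slope_volume = NULL,
                            tcc_t0 = NULL, tcc_slope_time = NULL,
                            cellcount_beta0 = 352.0, cellcount_beta1 = 7261.3,
                            v0 = 0.1, noise_sd_tcc = 1, noise_sd_cells = 530) {
  has_volume_law <- !is.null(tcc_slope_volume)
  has_time_law <- !is.null(tcc_t0) || !is.null(tcc_slope_time)
  if (!has_volume_law && !has_time_law) {
    stop("genotype_params(): supply a volume law (tcc_intercept + ",
         "tcc_slope_volume) or a time law (tcc_t0 + tcc_slope_time)",
         call. = FALSE)
  }
  if (has_volume_law && is.null(tcc_intercept)) {
    stop("genotype_params(): volume law needs tcc_intercept", call. = FALSE)
  }
  if (!has_volume_law && (is.null(tcc_t0) || is.null(tcc_slope_time))) {
    stop("genotype_params(): time law needs both tcc_t0 and tcc_slope_time",
         call. = FALSE)
  }
  vals <- c(tcc_intercept, tcc_slope_volume, tcc_t0, tcc_slope_time,
            cellcount_beta0, cellcount_beta1, v0)
  if (any(!is.finite(vals))) {
    stop("genotype_params(): all coefficients must be finite", call. = FALSE)
  }
  if (v0 <= 0) stop("genotype_params(): v0 must be positive", call. = FALSE)
  if (noise_sd_tcc < 0 || noise_sd_cells < 0) {
    stop("genotype_params(): noise SDs must be non-negative", call. = FALSE)
  }
  structure(
    list(name = name,
         law = if (has_volume_law) "volume" else "time",
         tcc_intercept = tcc_intercept, tcc_slope_volume = tcc_slope_volume,
         tcc_t0 = tcc_t0, tcc_slope_time = tcc_slope_time,
         cellcount_beta0 = cellcount_beta0, cellcount_beta1 = cellcount_beta1,
         v0 = v0, noise_sd_tcc = noise_sd_tcc, noise_sd_cells = noise_sd_cells),
    class = "genotype_params"
  )
}

# true cell-cycle time under the genotype's law
tcc_true <- function(params, t, v) {
  if (params$law == "volume") {
    params$tcc_intercept + params$tcc_slope_volume * v
  } else {
    params$tcc_t0 + params$tcc_slope_time * t
  }
}

#' Preset genotype parameter sets
#'
#' `wildtype` uses the nub-Gal4 control values: scaling coefficient
#' 16 hr/nL, 8 hr cell cycle at zero volume, and the cell-count conversion
#' 352.0 + 7261.3 cells/nL. `ds_rnai` mimics a Dachsous knockdown: a halved
#' scaling coefficient (8 hr/nL) and the conversion 653.9 + 4533.5 cells/nL.
#' Cell-count residual SDs are set so the conversion regression has
#' R-squared near 0.95 over the 0.1-1.2 nL design spread.
#'
#' @return Named list of [genotype_params()].
#' @export
genotype_presets <- function() {
  list(
    wildtype = genotype_params(
      name = "wildtype", tcc_intercept = 8, tcc_slope_volume = 16,
      cellcount_beta0 = 352.0, cellcount_beta1 = 7261.3,
      v0 = 0.1, noise_sd_tcc = 1, noise_sd_cells = 530
    ),
    ds_rnai = genotype_params(
      name = "ds_rnai", tcc_intercept = 8, tcc_slope_volume = 8,
      cellcount_beta0 = 653.9, cellcount_beta1 = 4533.5,
      v0 = 0.1, noise_sd_tcc = 1, noise_sd_cells = 330
    )
  )
}

#' Generate growing pouch records with known cell-cycle ground truth
#'
#' Grows a mean pouch volume from `params$v0` by the discrete recursion
#' `V_t = (1 + ln(2)/tcc * dt) * V_(t-dt)` with the cell-cycle time given by
#' the genotype's law, then emits `n_per_age` specimens at each requested
#' age with multiplicative lognormal volume jitter. The true cell-cycle
#' time of each specimen (evaluated at its own jittered volume under the
#' volume law, or at its age under the time law) is stored as hidden ground
#' truth in `tcc_true_hr`. Areas and thickness are back-filled so that
#' [pouch_volume()] reproduces `volume_nl` exactly.
#'
#' @param params A [genotype_params()].
#' @param ages Sorted ages (hr) at which specimens are sampled.
#' @param n_per_age Specimens per age.
#' @param seed Integer seed.
#' @param volume_jitter_sdlog SD of the lognormal volume jitter (log scale).
#' @param dt Recursion step in hours.
#' @param tm M-phase duration (hr); generated cell-cycle times must exceed it.
#' @return Tibble of pouch records with hidden-truth columns `tcc_true_hr`
#'   and `volume_mean_nl`.
#' @export
gen_pouch_growth <- function(params, ages = seq(0, 36, by = 4), n_per_age = 5,
                             seed = 1L, volume_jitter_sdlog = 0.1, dt = 1,
                             tm = 0.34) {
  stopifnot(inherits(params, "genotype_params"))
  if (is.unsorted(ages)) stop("gen_pouch_growth(): ages must be sorted", call. = FALSE)
  if (n_per_age < 1) stop("gen_pouch_growth(): n_per_age must be >= 1", call. = FALSE)
  # mean trajectory from t = 0 to the last age
  times <- seq(0, max(ages), by = dt)
  vmean <- numeric(length(times))
  vmean[1] <- params$v0
  for (k in seq_along(times)[-1]) {
    tcc_k <- tcc_true(params, times[k], vmean[k - 1])
    if (tcc_k <= tm) {
      stop("gen_pouch_growth(): cell-cycle time fell to or below the M-phase ",
           "duration; unphysical parameters", call. = FALSE)
    }
    vmean[k] <- (1 + log(2) / tcc_k * dt) * vmean[k - 1]
  }
  v_at_age <- stats::approx(times, vmean, xout = ages)$y
  withr::with_seed(seed, {
    out <- purrr::map2_dfr(ages, v_at_age, function(a, vm) {
      jitter <- if (volume_jitter_sdlog > 0) {
        exp(stats::rnorm(n_per_age, 0, volume_jitter_sdlog))
      } else rep(1, n_per_age)
      v <- vm * jitter
      tibble::tibble(
        age_hr = a, genotype = params$name, stage = "L3",
        volume_mean_nl = vm, volume_nl = v,
        tcc_true_hr = tcc_true(params, a, v)
      )
    })
  })
  if (any(out$tcc_true_hr <= tm)) {
    stop("gen_pouch_growth(): jittered specimen has unphysical cell-cycle time",
         call. = FALSE)
  }
  out$pouch_id <- sprintf("%s_t%03d_%02d", params$name,
                          as.integer(round(out$age_hr)),
                          stats::ave(seq_len(nrow(out)), out$age_hr, FUN = seq_along))
  # geometry consistent with volume: fixed thickness, areas split 70/15/15
  out$thickness_um <- 25
  total_area <- out$volume_nl * 1e6 / out$thickness_um
  out$apical_area_um2 <- 0.7 * total_area
  out$basal_area_dorsal_um2 <- 0.15 * total_area
  out$basal_area_ventral_um2 <- 0.15 * total_area
  dplyr::relocate(out, "pouch_id")
}

#' Sample the cell-cycle scaling relationship directly
#'
#' Draws pouch volumes uniformly over a design range and generates observed
#' cell-cycle times from the genotype's volume law plus Gaussian noise
#' (`noise_sd_tcc`). This is the design used for scaling-coefficient
#' recovery simulations.
#'
#' @param params A [genotype_params()] with a volume law.
#' @param n Number of pouches.
#' @param volume_range Uniform design range in nL.
#' @param seed Integer seed.
#' @return Tibble with `volume_nl`, hidden truth `tcc_true_hr`, and noisy
#'   `tcc_hr`.
#' @export
gen_scaling_dataset <- function(params, n = 50, volume_range = c(0.1, 1.1),
                                seed = 1L) {
  stopifnot(inherits(params, "genotype_params"))
  if (params$law != "volume") {
    stop("gen_scaling_dataset(): params must carry a volume law", call. = FALSE)
  }
  withr::with_seed(seed, {
    v <- stats::runif(n, volume_range[1], volume_range[2])
    tcc0 <- tcc_true(params, t = NA_real_, v = v)
    tibble::tibble(
      pouch_id = sprintf("%s_%03d", params$name, seq_len(n)),
      genotype = params$name,
      volume_nl = v,
      tcc_true_hr = tcc0,
      tcc_hr = tcc0 + stats::rnorm(n, 0, params$noise_sd_tcc)
    )
  })
}

#' Sample the cell-number-vs-volume relationship directly
#'
#' Draws pouch volumes uniformly and generates total cell counts from the
#' genotype's linear conversion plus Gaussian noise (`noise_sd_cells`),
#' rounded and floored at 1 cell. This is the design used for conversion
#' model recovery simulations.
#'
#' @inheritParams gen_scaling_dataset
#' @param volume_range Uniform design range in nL.
#' @return Tibble with `volume_nl` and `total_cells`.
#' @export
gen_cellcount_dataset <- function(params, n = 30, volume_range = c(0.1, 1.2),
                                  seed = 1L) {
  stopifnot(inherits(params, "genotype_params"))
  withr::with_seed(seed, {
    v <- stats::runif(n, volume_range[1], volume_range[2])
    counts <- params$cellcount_beta0 + params$cellcount_beta1 * v +
      stats::rnorm(n, 0, params$noise_sd_cells)
    tibble::tibble(
      pouch_id = sprintf("%s_%03d", params$name, seq_len(n)),
      genotype = params$name,
      volume_nl = v,
      total_cells = pmax(1L, as.integer(round(counts)))
    )
  })
}

#' Generate PHH3 mitotic samples for pouch records
#'
#' For each pouch, the total cell number is drawn from the genotype's
#' linear conversion with Gaussian noise (rounded, floored at 1). Each cell
#' is independently in M phase with probability `tm / tcc_true_hr`, so the
#' PHH3 count is binomial. A segmented subdomain covering
#' `subdomain_fraction` of the pouch area receives a binomial share of the
#' cells, making the subdomain density consistent with the total count.
#'
#' @param records Pouch records with `pouch_id`, `volume_nl`, `tcc_true_hr`
#'   and (optionally) area/thickness columns used to derive the 2D pouch
#'   area; without them the area is taken as volume / 25 um thickness.
#' @param tm M-phase duration in hours (default 0.34).
#' @param params A [genotype_params()] providing the cell-count conversion.
#' @param seed Integer seed.
#' @param subdomain_fraction Fraction of the pouch area that is segmented.
#' @return Tibble of mitotic samples (one per record) with hidden truth
#'   `total_cells_true`.
#' @export
gen_mitotic_counts <- function(records, tm = 0.34, params, seed = 1L,
                               subdomain_fraction = 0.1) {
  stopifnot(inherits(params, "genotype_params"))
  if (tm <= 0) stop("gen_mitotic_counts(): tm must be positive", call. = FALSE)
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(
      pouch_id = character(), phh3_count = integer(),
      subdomain_cell_count = integer(), subdomain_area_um2 = numeric(),
      pouch_area_um2 = numeric(), total_cells_true = integer()
    ))
  }
  require_columns(records, c("pouch_id", "volume_nl", "tcc_true_hr"),
                  "gen_mitotic_counts")
  if (any(records$tcc_true_hr <= tm)) {
    stop("gen_mitotic_counts(): tm >= true cell-cycle time; mitotic index ",
         "would exceed 1", call. = FALSE)
  }
  area_cols <- c("apical_area_um2", "basal_area_dorsal_um2", "basal_area_ventral_um2")
  pouch_area <- if (all(area_cols %in% names(records))) {
    rowSums(as.matrix(records[area_cols]))
  } else {
    records$volume_nl * 1e6 / 25
  }
  withr::with_seed(seed, {
    n_true <- pmax(1L, as.integer(round(
      params$cellcount_beta0 + params$cellcount_beta1 * records$volume_nl +
        stats::rnorm(nrow(records), 0, params$noise_sd_cells)
    )))
    phh3 <- stats::rbinom(nrow(records), n_true, tm / records$tcc_true_hr)
    sub_n <- stats::rbinom(nrow(records), n_true, subdomain_fraction)
    tibble::tibble(
      pouch_id = records$pouch_id,
      phh3_count = phh3,
      subdomain_cell_count = sub_n,
      subdomain_area_um2 = subdomain_fraction * pouch_area,
      pouch_area_um2 = pouch_area,
      total_cells_true = n_true
    )
  })
}

#' Generate a two-phase allometry series
#'
#' Body weights are drawn uniformly over `weight_range`; log10 pouch volume
#' is a continuous piecewise-linear (hinge) function of log10 body weight
#' with slopes `phase1_slope` then `phase2_slope` and a breakpoint at
#' `break_weight`, plus Gaussian noise in log10 units.
#'
#' @param phase1_slope,phase2_slope Log-log allometric slopes (> 0).
#' @param break_weight Hinge position in mg; must fall inside the generated
#'   weight range.
#' @param n Number of paired observations (>= 6).
#' @param noise_sd Gaussian noise SD in log10 units.
#' @param seed Integer seed.
#' @param weight_range Uniform body-weight range in mg.
#' @param log10_volume_at_1mg Log10 pouch volume (nL) at 1 mg body weight.
#' @return Tibble with `body_weight_mg`, `pouch_volume_nl` and hidden truth
#'   `log10_volume_true`.
#' @export
gen_allometry_series <- function(phase1_slope, phase2_slope, break_weight,
                                 n = 60, noise_sd = 0.05, seed = 1L,
                                 weight_range = c(0.5, 2.0),
                                 log10_volume_at_1mg = log10(0.3)) {
  if (n < 6) stop("gen_allometry_series(): need n >= 6", call. = FALSE)
  if (phase1_slope <= 0 || phase2_slope <= 0) {
    stop("gen_allometry_series(): slopes must be positive", call. = FALSE)
  }
  withr::with_seed(seed, {
    w <- stats::runif(n, weight_range[1], weight_range[2])
    if (break_weight <= min(w) || break_weight >= max(w)) {
      stop("gen_allometry_series(): break_weight outside the generated ",
           "weight range", call. = FALSE)
    }
    x <- log10(w)
    b <- log10(break_weight)
    y_true <- log10_volume_at_1mg + phase1_slope * x +
      (phase2_slope - phase1_slope) * pmax(x - b, 0)
    y <- y_true + stats::rnorm(n, 0, noise_sd)
    tibble::tibble(
      specimen_id = sprintf("allo_%03d", seq_len(n)),
      body_weight_mg = w,
      pouch_volume_nl = 10^y,
      log10_volume_true = y_true
    )
  })
}

#' Generate synthetic larval morphometrics
#'
#' Midline lengths are uniform over `length_range`; mean widths are
#' `length / aspect` with multiplicative lognormal jitter. The hidden true
#' volume is the cylinder volume computed from the jittered width, so
#' [larval_volume()] reproduces it exactly.
#'
#' @param n Number of larvae (>= 1).
#' @param length_range Midline length range in um.
#' @param aspect Length-to-width ratio.
#' @param seed Integer seed.
#' @param width_jitter_sdlog SD of the lognormal width jitter.
#' @return Tibble of specimen records with hidden truth `volume_true_nl`.
#' @export
gen_larvae <- function(n, length_range = c(3000, 5000), aspect = 4, seed = 1L,
                       width_jitter_sdlog = 0.05) {
  if (n < 1) stop("gen_larvae(): need n >= 1", call. = FALSE)
  withr::with_seed(seed, {
    len <- stats::runif(n, length_range[1], length_range[2])
    width <- len / aspect * exp(stats::rnorm(n, 0, width_jitter_sdlog))
    tibble::tibble(
      specimen_id = sprintf("larva_%03d", seq_len(n)),
      midline_length_um = len,
      mean_width_um = width,
      volume_true_nl = pi * (width / 2)^2 * len / 1e6
    )
  })
}
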