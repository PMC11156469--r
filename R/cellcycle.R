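#' Estimate total pouch cell number from a segmented subdomain
#'
#' Cell density in a segmented subdomain (segmented cell count divided by
#' subdomain area) is multiplied by the total pouch area to estimate the
#' total number of pouch cells, rounded to the nearest integer.
#'
#' @param data Data frame of mitotic samples with columns
#'   `subdomain_cell_count`, `subdomain_area_um2`, `pouch_area_um2`.
#' @return Tibble with a `total_cells` column appended.
#' @export
estimate_total_cells <- function(data) {
  require_columns(data,
                  c("subdomain_cell_count", "subdomain_area_um2", "pouch_area_um2"),
                  "estimate_total_cells")
  if (any(data$subdomain_area_um2 <= 0)) {
    stop("estimate_total_cells(): subdomain_area_um2 must be positive", call. = FALSE)
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    total_cells = as.integer(round(
      .data$subdomain_cell_count / .data$subdomain_area_um2 * .data$pouch_area_um2
    ))
  )
}

#' Fit a linear cell-number-vs-volume conversion model
#'
#' Ordinary least squares of total cell number on pouch volume,
#' `total_cells = beta0 + beta1 * volume_nl`. The fitted coefficients play
#' the role of a genotype-specific conversion factor from pouch volume to
#' cell number.
#'
#' @param data Data frame with columns `volume_nl` and `total_cells`.
#' @param genotype Optional genotype label stored with the fit (taken from a
#'   `genotype` column when present).
#' @return A `cellcount_model` object with fields `beta0`, `beta1`,
#'   `se_beta0`, `se_beta1`, `r_squared`, `p_value` (slope) and `n`.
#' @export
fit_cellcount_model <- function(data, genotype = NULL) {
  require_columns(data, c("volume_nl", "total_cells"), "fit_cellcount_model")
  data <- tibble::as_tibble(data)
  if (nrow(data) < 3) {
    stop("fit_cellcount_model(): need at least 3 records", call. = FALSE)
  }
  if (length(unique(data$volume_nl)) < 2) {
    stop("fit_cellcount_model(): degenerate design, volumes are all equal",
         call. = FALSE)
  }
  if (is.null(genotype) && "genotype" %in% names(data)) {
    genotype <- as.character(unique(data$genotype))[1]
  }
  fit <- stats::lm(total_cells ~ volume_nl, data = data)
  sm <- quiet_summary(fit)
  structure(
    list(
      genotype  = genotype %||% NA_character_,
      beta0     = unname(stats::coef(fit)[1]),
      beta1     = unname(stats::coef(fit)[2]),
      se_beta0  = sm$coefficients[1, "Std. Error"],
      se_beta1  = sm$coefficients[2, "Std. Error"],
      r_squared = sm$r.squared,
      p_value   = sm$coefficients[2, "Pr(>|t|)"],
      n         = nrow(data),
      model     = fit
    ),
    class = "cellcount_model"
  )
}

#' Predict total cell number from pouch volume
#'
#' @param volume_nl Pouch volume(s) in nL; must be non-negative.
#' @param model A `cellcount_model` (or any list with `beta0` and `beta1`).
#' @return Integer vector of predicted cell numbers (rounded).
#' @export
cells_from_volume <- function(volume_nl, model) {
  if (any(volume_nl < 0)) {
    stop("cells_from_volume(): volumes must be non-negative", call. = FALSE)
  }
  pred <- model$beta0 + model$beta1 * volume_nl
  if (any(pred < 0)) {
    stop("cells_from_volume(): negative predicted cell number; ",
         "volume outside the model's calibrated range", call. = FALSE)
  }
  as.integer(round(pred))
}

#' Mitotic index
#'
#' Fraction of cells in M phase at fixation: PHH3-positive cells divided by
#' total cells.
#'
#' @param phh3_count Number of PHH3-positive (M-phase) cells.
#' @param total_cells Total cell number (must be >= `phh3_count`).
#' @return Numeric vector of mitotic indices in \[0, 1\].
#' @export
mitotic_index <- function(phh3_count, total_cells) {
  if (any(total_cells <= 0)) {
    stop("mitotic_index(): total_cells must be positive", call. = FALSE)
  }
  if (any(phh3_count < 0) || any(phh3_count > total_cells)) {
    stop("mitotic_index(): phh3_count must lie in [0, total_cells]", call. = FALSE)
  }
  phh3_count / total_cells
}

#' Average cell-cycle time from the mitotic index
#'
#' Under uniform asynchronous proliferation, the fraction of cells in M phase
#' equals the ratio of M-phase duration to total cycle duration, so the
#' average cell-cycle time is the M-phase transit time divided by the mitotic
#' index. The default M-phase transit time is 0.34 hr (20.5 min), the
#' live-imaging estimate for third-instar wing pouch cells.
#'
#' @param mi Mitotic index, in (0, 1].
#' @param tm M-phase transit time in hours (default 0.34).
#' @return Cell-cycle time(s) in hours.
#' @export
cell_cycle_time <- function(mi, tm = 0.34) {
  if (tm <= 0) stop("cell_cycle_time(): tm must be positive", call. = FALSE)
  if (any(mi <= 0) || any(mi > 1)) {
    stop("cell_cycle_time(): mitotic index must lie in (0, 1]; ",
         "a zero index leaves the cell-cycle time unbounded", call. = FALSE)
  }
  tm / mi
}

#' Instantaneous exponential growth rate from cell-cycle time
#'
#' Assuming exponential growth with doubling time equal to the cell-cycle
#' time, the instantaneous per-hour rate is `ln(2) / tcc`.
#'
#' @param tcc_hr Cell-cycle time(s) in hours.
#' @return Growth rate(s) per hour.
#' @export
growth_rate <- function(tcc_hr) {
  if (any(tcc_hr <= 0)) {
    stop("growth_rate(): cell-cycle time must be positive", call. = FALSE)
  }
  log(2) / tcc_hr
}

#' Per-pouch cell-cycle estimates from pouch and mitotic tables
#'
#' Joins pouch records with their mitotic samples and runs the inference
#' chain: total cells from subdomain density, mitotic index, cell-cycle time
#' (`tm / MI`), and instantaneous growth rate. Pouches with zero PHH3 counts
#' have an undefined (infinite) cell-cycle time; they are returned with
#' `tcc_hr = NA` and a warning, and should be excluded from regressions.
#'
#' @param pouches Data frame with `pouch_id`, `volume_nl` and usually
#'   `age_hr`, `genotype`.
#' @param mitotic Data frame with `pouch_id`, `phh3_count`,
#'   `subdomain_cell_count`, `subdomain_area_um2`, `pouch_area_um2`.
#' @param tm M-phase transit time in hours (default 0.34).
#' @return Tibble with one row per pouch: `total_cells`, `mitotic_index`,
#'   `tcc_hr`, `growth_rate_per_hr` joined onto the pouch columns.
#' @export
estimate_cell_cycle <- function(pouches, mitotic, tm = 0.34) {
  require_columns(pouches, c("pouch_id", "volume_nl"), "estimate_cell_cycle")
  require_columns(mitotic, "phh3_count", "estimate_cell_cycle")
  mitotic <- estimate_total_cells(mitotic)
  keep <- intersect(names(pouches),
                    c("pouch_id", "volume_nl", "age_hr", "genotype", "stage"))
  out <- dplyr::inner_join(tibble::as_tibble(pouches)[keep],
                           mitotic[c("pouch_id", "phh3_count", "total_cells")],
                           by = "pouch_id")
  if (nrow(out) == 0) {
    stop("estimate_cell_cycle(): no pouch ids shared between tables", call. = FALSE)
  }
  # density estimation can undershoot the PHH3 count in tiny pouches; such
  # rows (like zero-PHH3 rows) carry no usable index and are flagged NA
  invalid <- out$total_cells <= 0 | out$phh3_count > out$total_cells
  if (any(invalid)) {
    warning(sum(invalid), " pouch(es) with PHH3 counts exceeding the ",
            "estimated cell number: mitotic index set to NA", call. = FALSE)
  }
  out$mitotic_index <- NA_real_
  out$mitotic_index[!invalid] <-
    mitotic_index(out$phh3_count[!invalid], out$total_cells[!invalid])
  zero <- !is.na(out$mitotic_index) & out$mitotic_index == 0
  if (any(zero)) {
    warning(sum(zero), " pouch(es) with zero PHH3 counts: cell-cycle time ",
            "undefined, set to NA", call. = FALSE)
  }
  zero <- zero | invalid
  out$tcc_hr <- NA_real_
  out$tcc_hr[!zero] <- cell_cycle_time(out$mitotic_index[!zero], tm = tm)
  out$growth_rate_per_hr <- ifelse(zero, NA_real_, log(2) / out$tcc_hr)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
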