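#' Larval body volume from length and width
#'
#' Approximates a larva as a cylinder whose height is the measured midline
#' length and whose diameter is the mean body width, and returns the volume
#' in nanolitres (1 nL = 1e6 um^3).
#'
#' @param midline_length_um Midline (skeleton) length in micrometres.
#' @param mean_width_um Mean body width (cylinder diameter) in micrometres.
#' @return Numeric vector of volumes in nL.
#' @examples
#' larval_volume(4000, 1000) # pi * 500^2 * 4000 / 1e6 ~= 3141.6 nL
#' @export
larval_volume <- function(midline_length_um, mean_width_um) {
  if (any(!is.finite(midline_length_um)) || any(!is.finite(mean_width_um))) {
    stop("larval_volume(): lengths and widths must be finite", call. = FALSE)
  }
  if (any(midline_length_um <= 0) || any(mean_width_um <= 0)) {
    stop("larval_volume(): lengths and widths must be positive", call. = FALSE)
  }
  pi * (mean_width_um / 2)^2 * midline_length_um / 1e6
}

#' Add cylinder body volumes to a larval morphometrics table
#'
#' @param data Data frame with columns `midline_length_um` and `mean_width_um`.
#' @return The input as a tibble with a `body_volume_nl` column appended.
#' @export
add_larval_volumes <- function(data) {
  require_columns(data, c("midline_length_um", "mean_width_um"), "add_larval_volumes")
  dplyr::mutate(
    tibble::as_tibble(data),
    body_volume_nl = larval_volume(.data$midline_length_um, .data$mean_width_um)
  )
}

#' Wing-pouch volume from surface areas and thickness
#'
#' Pouch volume is the pouch thickness (measured at the AP/DV midline
#' intersection) multiplied by the total surface area. In late discs the
#' pouch folds under itself, so the apical area and the two basal
#' (dorsal/ventral) areas are measured independently and summed; for
#' immature discs without deep folds the basal areas are absent and are
#' treated as zero. Volumes are reported in nL (um^3 / 1e6).
#'
#' @param data Data frame of pouch records with columns `apical_area_um2`
#'   and `thickness_um`; optional `basal_area_dorsal_um2`,
#'   `basal_area_ventral_um2`.
#' @return The input as a tibble with a `volume_nl` column appended.
#' @export
pouch_volume <- function(data) {
  require_columns(data, c("apical_area_um2", "thickness_um"), "pouch_volume")
  data <- tibble::as_tibble(data)
  for (col in c("basal_area_dorsal_um2", "basal_area_ventral_um2")) {
    if (!col %in% names(data)) data[[col]] <- 0
    data[[col]][is.na(data[[col]])] <- 0
  }
  if (any(is.na(data$thickness_um)) || any(data$thickness_um <= 0)) {
    stop("pouch_volume(): thickness_um must be present and positive for every record",
         call. = FALSE)
  }
  areas <- cbind(data$apical_area_um2, data$basal_area_dorsal_um2,
                 data$basal_area_ventral_um2)
  if (any(areas < 0)) {
    stop("pouch_volume(): surface areas must be non-negative", call. = FALSE)
  }
  dplyr::mutate(
    data,
    volume_nl = .data$thickness_um *
      (.data$apical_area_um2 + .data$basal_area_dorsal_um2 +
         .data$basal_area_ventral_um2) / 1e6
  )
}

#' Compartment area ratios
#'
#' Computes the ratio of two compartment areas (e.g. dorsal/ventral) per
#' pouch, optionally normalized to the mean ratio of a control group so the
#' control group averages 1.
#'
#' @param data Data frame with per-compartment area columns named
#'   `area_<compartment>_um2` (compartments `a`, `p`, `d`, `v`) and,
#'   when `normalize_to` is used, a `genotype` column.
#' @param numerator,denominator Compartment letters.
#' @param normalize_to Optional genotype label; ratios are divided by the
#'   mean ratio of that group.
#' @return Tibble with a `compartment_ratio` column appended.
#' @export
compartment_ratio <- function(data, numerator = "d", denominator = "v",
                              normalize_to = NULL) {
  num_col <- paste0("area_", tolower(numerator), "_um2")
  den_col <- paste0("area_", tolower(denominator), "_um2")
  require_columns(data, c(num_col, den_col), "compartment_ratio")
  data <- tibble::as_tibble(data)
  if (any(is.na(data[[num_col]])) || any(is.na(data[[den_col]]))) {
    stop("compartment_ratio(): missing compartment areas", call. = FALSE)
  }
  if (any(data[[den_col]] <= 0)) {
    stop("compartment_ratio(): denominator compartment areas must be positive",
         call. = FALSE)
  }
  data$compartment_ratio <- data[[num_col]] / data[[den_col]]
  if (!is.null(normalize_to)) {
    require_columns(data, "genotype", "compartment_ratio")
    ctrl <- data$compartment_ratio[data$genotype == normalize_to]
    if (length(ctrl) == 0) {
      stop("compartment_ratio(): no records with genotype '", normalize_to, "'",
           call. = FALSE)
    }
    data$compartment_ratio <- data$compartment_ratio / mean(ctrl)
  }
  data
}

# internal: fail with the missing column names
require_columns <- function(data, cols, fn) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop(fn, "(): missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(data)
}
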