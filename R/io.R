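# Table dialects shared by the pipeline. Each schema lists the required
# columns with their types and the columns that must be non-negative.
table_schemas <- list(
  larvae = list(
    required = c(specimen_id = "character", midline_length_um = "numeric",
                 mean_width_um = "numeric"),
    positive = c("midline_length_um", "mean_width_um")
  ),
  pouches = list(
    required = c(pouch_id = "character", age_hr = "numeric",
                 genotype = "character", apical_area_um2 = "numeric",
                 thickness_um = "numeric"),
    positive = c("thickness_um"),
    nonneg = c("apical_area_um2", "basal_area_dorsal_um2",
               "basal_area_ventral_um2", "age_hr")
  ),
  mitotic = list(
    required = c(pouch_id = "character", phh3_count = "numeric",
                 subdomain_cell_count = "numeric",
                 subdomain_area_um2 = "numeric", pouch_area_um2 = "numeric"),
    positive = c("subdomain_area_um2", "pouch_area_um2"),
    nonneg = c("phh3_count", "subdomain_cell_count")
  ),
  allometry = list(
    required = c(body_weight_mg = "numeric", pouch_volume_nl = "numeric"),
    positive = c("body_weight_mg", "pouch_volume_nl")
  ),
  estimates = list(
    required = c(pouch_id = "character", volume_nl = "numeric",
                 tcc_hr = "numeric"),
    positive = character()
  ),
  profile = list(
    required = c(position = "numeric", mean_intensity = "numeric"),
    positive = character()
  ),
  trajectory = list(
    required = c(time_hr = "numeric", volume_nl = "numeric"),
    positive = c("volume_nl")
  ),
  midline = list(
    required = c(x_px = "numeric", y_px = "numeric"),
    positive = character()
  )
)

SCHEMA_VERSION <- "1.0"

#' Read and validate a pipeline CSV table
#'
#' Reads a CSV in one of the package's documented dialects and validates it
#' against the schema: missing required columns, non-numeric cells in
#' numeric columns, and negative values in columns that must be
#' non-negative are all errors naming the offending row and column. An
#' empty file with a valid header yields an empty tibble.
#'
#' @param path CSV path.
#' @param schema One of `"larvae"`, `"pouches"`, `"mitotic"`,
#'   `"allometry"`, `"estimates"`, `"profile"`, `"trajectory"`, `"midline"`.
#' @return A validated tibble.
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, names(table_schemas))
  sc <- table_schemas[[schema]]
  if (!file.exists(path)) {
    stop("read_table(): file not found: ", path, call. = FALSE)
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(names(sc$required), names(data))
  if (length(missing) > 0) {
    stop("read_table(): ", schema, " table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- union(names(sc$required)[sc$required == "numeric"],
                    intersect(names(data), c(sc$positive, sc$nonneg)))
  for (col in intersect(num_cols, names(data))) {
    raw <- data[[col]]
    if (!is.numeric(raw)) {
      num <- suppressWarnings(as.numeric(as.character(raw)))
      bad <- which(is.na(num) & !is.na(raw) & raw != "NA")
      if (length(bad) > 0) {
        stop("read_table(): non-numeric value '", raw[bad[1]], "' in column '",
             col, "', row ", bad[1], call. = FALSE)
      }
      data[[col]] <- num
    }
  }
  for (col in intersect(sc$positive, names(data))) {
    bad <- which(!is.na(data[[col]]) & data[[col]] <= 0)
    if (length(bad) > 0) {
      stop("read_table(): column '", col, "' must be positive; row ", bad[1],
           " has ", data[[col]][bad[1]], call. = FALSE)
    }
  }
  for (col in intersect(sc$nonneg, names(data))) {
    bad <- which(!is.na(data[[col]]) & data[[col]] < 0)
    if (length(bad) > 0) {
      stop("read_table(): column '", col, "' must be non-negative; row ",
           bad[1], " has ", data[[col]][bad[1]], call. = FALSE)
    }
  }
  attr(data, "schema") <- schema
  attr(data, "schema_version") <- SCHEMA_VERSION
  data
}

#' Write a pipeline CSV table
#'
#' @param data Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

#' Read a single-channel TIFF image as an intensity matrix
#'
#' @param path TIFF path.
#' @param max_value Full-scale intensity the stored \[0, 1\] values map to
#'   (default 65535 for 16-bit).
#' @return Numeric matrix (rows = y, columns = x).
#' @export
read_gradient_image <- function(path, max_value = 65535) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * max_value
}

#' Write an intensity matrix as a 16-bit single-channel TIFF
#'
#' @param image Numeric matrix; values are clipped to \[0, max_value\].
#' @param path Output path.
#' @param max_value Full-scale intensity (default 65535).
#' @return `path`, invisibly.
#' @export
write_gradient_image <- function(image, path, max_value = 65535) {
  scaled <- pmin(pmax(image / max_value, 0), 1)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a midline polyline CSV
#'
#' @param path CSV with ordered `x_px`, `y_px` columns.
#' @param pixel_size Pixel size in um/px.
#' @param center_index Centre-point index; defaults to the point midway
#'   along the arc.
#' @return A [midline()].
#' @export
read_midline <- function(path, pixel_size, center_index = NULL) {
  pts <- read_table(path, "midline")
  if (is.null(center_index)) {
    d <- cumsum(c(0, sqrt(diff(pts$x_px)^2 + diff(pts$y_px)^2)))
    center_index <- which.min(abs(d - max(d) / 2))
  }
  midline(pts$x_px, pts$y_px, pixel_size, center_index)
}

#' Write a midline polyline CSV
#'
#' @param line A [midline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_midline <- function(line, path) {
  readr::write_csv(tibble::tibble(x_px = line$x_px, y_px = line$y_px), path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Every pipeline stage records its command, inputs, outputs, seed and
#' parameters so each artifact is reproducible from its manifest alone.
#'
#' @param path Output path.
#' @param command Stage name.
#' @param inputs,outputs Character vectors of file paths.
#' @param seed Integer seed used by the stage.
#' @param parameters Named list of stage parameters.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, inputs = character(),
                           outputs = character(), seed = NA_integer_,
                           parameters = list()) {
  manifest <- list(
    command = command,
    schema_version = SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("wingscaling")),
    seed = seed,
    inputs = as.list(inputs),
    outputs = as.list(outputs),
    parameters = parameters
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
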