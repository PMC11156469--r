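#' Run one stage of the analysis pipeline from a configuration
#'
#' Thin orchestration over the package's functions, suitable for driving
#' from a shell script or a YAML file. A configuration holds:
#'
#' * `command`: one of `generate`, `infer-tcc`, `fit-scaling`,
#'   `fit-allometry`, `simulate-growth`, `profiles`;
#' * `out_dir`: output directory (created if needed);
#' * `seed`: integer seed recorded in the manifest and used by any
#'   stochastic stage;
#' * `inputs`: named list of input file paths (stage-dependent);
#' * `params`: named list of stage parameter overrides.
#'
#' Unknown top-level keys are rejected. Every stage writes its artifacts
#' plus a JSON manifest (command, inputs, outputs, seed, parameters), and is
#' deterministic for a fixed seed.
#'
#' @param config A list as above, or the path of a YAML file holding one.
#' @return Invisibly, a character vector of written artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  allowed <- c("command", "out_dir", "seed", "inputs", "params")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0) {
    stop("run_pipeline(): unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  commands <- c("generate", "infer-tcc", "fit-scaling", "fit-allometry",
                "simulate-growth", "profiles")
  if (is.null(config$command) || !config$command %in% commands) {
    stop("run_pipeline(): command must be one of: ",
         paste(commands, collapse = ", "), call. = FALSE)
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  inputs <- config$inputs %||% list()
  params <- config$params %||% list()
  outputs <- switch(
    config$command,
    "generate" = stage_generate(out_dir, seed, params),
    "infer-tcc" = stage_infer_tcc(out_dir, inputs, params),
    "fit-scaling" = stage_fit_scaling(out_dir, inputs),
    "fit-allometry" = stage_fit_allometry(out_dir, inputs, params),
    "simulate-growth" = stage_simulate_growth(out_dir, inputs, seed, params),
    "profiles" = stage_profiles(out_dir, inputs, params)
  )
  manifest <- file.path(out_dir, paste0(gsub("-", "_", config$command),
                                        "_manifest.json"))
  write_manifest(manifest, config$command,
                 inputs = unlist(inputs, use.names = FALSE),
                 outputs = outputs, seed = seed, parameters = params)
  invisible(c(outputs, manifest))
}

stage_generate <- function(out_dir, seed, params) {
  presets <- genotype_presets()
  gname <- params$genotype %||% "wildtype"
  if (!gname %in% names(presets)) {
    stop("generate: unknown genotype preset '", gname, "'", call. = FALSE)
  }
  gp <- presets[[gname]]
  ages <- params$ages %||% seq(0, 36, by = 4)
  pouches <- gen_pouch_growth(gp, ages = ages,
                              n_per_age = params$n_per_age %||% 5,
                              seed = seed)
  mitotic <- gen_mitotic_counts(pouches, tm = params$tm %||% 0.34,
                                params = gp, seed = seed + 1L)
  p1 <- file.path(out_dir, "pouches.csv")
  p2 <- file.path(out_dir, "mitotic.csv")
  write_table(pouches, p1)
  write_table(mitotic, p2)
  c(p1, p2)
}

stage_infer_tcc <- function(out_dir, inputs, params) {
  pouches <- read_table(inputs$pouches, "pouches")
  if (!"volume_nl" %in% names(pouches)) pouches <- pouch_volume(pouches)
  mitotic <- read_table(inputs$mitotic, "mitotic")
  est <- estimate_cell_cycle(pouches, mitotic, tm = params$tm %||% 0.34)
  p <- file.path(out_dir, "estimates.csv")
  write_table(est, p)
  p
}

stage_fit_scaling <- function(out_dir, inputs) {
  est <- read_table(inputs$estimates, "estimates")
  fit <- fit_tcc_vs_volume(est)
  p <- file.path(out_dir, "scaling_fit.json")
  jsonlite::write_json(
    list(coefficients = tidy(fit), summary = glance(fit)),
    p, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  p
}

stage_fit_allometry <- function(out_dir, inputs, params) {
  data <- read_table(inputs$allometry, "allometry")
  fit <- fit_allometry(data, breakpoint = params$breakpoint,
                       two_phase = params$two_phase %||% TRUE)
  p <- file.path(out_dir, "allometry_fit.json")
  jsonlite::write_json(
    list(coefficients = tidy(fit), summary = glance(fit)),
    p, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  p
}

stage_simulate_growth <- function(out_dir, inputs, seed, params) {
  est <- read_table(inputs$estimates, "estimates")
  if (!"age_hr" %in% names(est)) {
    stop("simulate-growth: estimates table needs an age_hr column", call. = FALSE)
  }
  fit <- fit_tcc_vs_time(est)
  cfg <- growth_config(
    v0 = params$v0 %||% min(est$volume_nl),
    t_start = params$t_start %||% min(est$age_hr),
    t_end = params$t_end %||% max(est$age_hr),
    dt = params$dt %||% 1,
    n_draws = params$n_draws %||% 500,
    seed = seed
  )
  traj <- propagate_uncertainty(fit, cfg)
  p <- file.path(out_dir, "trajectory.csv")
  write_table(traj, p)
  p
}

stage_profiles <- function(out_dir, inputs, params) {
  image <- read_gradient_image(inputs$image)
  line <- read_midline(inputs$midline,
                       pixel_size = params$pixel_size %||% 0.25,
                       center_index = params$center_index)
  pp <- profile_params(
    orthogonal_halfwidth = params$orthogonal_halfwidth %||% 25,
    window_length = params$window_length %||% 100,
    sample_step = params$sample_step %||% 1
  )
  prof <- extract_profile(image, line, pp)
  p <- file.path(out_dir, "profile.csv")
  write_table(prof, p)
  p
}
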