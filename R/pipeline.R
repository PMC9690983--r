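# Configuration-driven pipeline stages tying the workflow together:
# synthesise -> calibrate -> demand -> simulate -> validate -> indicators ->
# risk. Each stage reads its inputs from the shared output directory (or
# paths in the config), writes machine-readable artifacts and a JSON metadata
# record carrying the seed and a config hash.

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$out_dir <- config$out_dir %||% "sprawlrisk_out"
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

write_meta <- function(cfg, stage, extra = list()) {
  meta <- c(list(stage = stage, seed = cfg$seed, config_hash = rlang::hash(cfg),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
  jsonlite::write_json(meta, file.path(cfg$out_dir, paste0(stage, "_meta.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

grid_path <- function(cfg, name) file.path(cfg$out_dir, paste0(name, ".asc"))

#' Run one pipeline stage from a configuration
#'
#' Stages (in workflow order): `"synth"` generates a synthetic region and its
#' reference growth; `"calibrate"` mines transition rules between the two maps
#' and writes per-class development-probability surfaces; `"demand"` estimates
#' (or loads) a transition matrix, optionally revises it toward a planning
#' target and projects class demand; `"simulate"` runs the cellular automaton
#' to the projected demand; `"validate"` scores the simulated map against the
#' observed one; `"indicators"` computes and grades the six ecological
#' indicators; `"risk"` assembles the zonal risk assessment.
#'
#' @param stage Stage name (see above).
#' @param config Path to a YAML file or a named list. Top-level keys:
#'   `out_dir`, `seed`, plus one optional section per stage (`synth`,
#'   `calibrate`, `simulate`, `demand`, `risk`, ...) holding that stage's
#'   parameters.
#' @return The stage's main result, invisibly; artifacts and a
#'   `<stage>_meta.json` (seed + config hash) are written under `out_dir`.
#' @export
run_stage <- function(stage = c("synth", "calibrate", "demand", "simulate",
                                "validate", "indicators", "risk"),
                      config = list()) {
  stage <- match.arg(stage)
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(stage,
    synth = stage_synth(cfg),
    calibrate = stage_calibrate(cfg),
    demand = stage_demand(cfg),
    simulate = stage_simulate(cfg),
    validate = stage_validate(cfg),
    indicators = stage_indicators(cfg),
    risk = stage_risk(cfg)
  )
  write_meta(cfg, stage)
  invisible(out)
}

stage_synth <- function(cfg) {
  p <- cfg$synth %||% list()
  nr <- p$n_rows %||% 120
  nc <- p$n_cols %||% 120
  # the reference growth recipe is stated at the 200 x 200 default scale;
  # smaller runs grow proportionally fewer cells
  scale <- (nr * nc) / (200 * 200)
  spec <- synthetic_spec(
    n_rows = nr, n_cols = nc,
    cell_size = p$cell_size %||% 30, seed = cfg$seed,
    growth = tibble::tibble(
      class = c("UB", "IM", "RS"),
      cells = pmax(20L, round(c(600L, 400L, 200L) * scale)),
      organic_frac = c(0.7, 0.5, 0.8),
      seeds = c(5L, 8L, 3L)
    )
  )
  region <- generate_region(spec)
  evolved <- evolve_reference_growth(region$map, region$drivers, spec)
  write_grid(region$map, grid_path(cfg, "map_t0"))
  write_grid(evolved$map, grid_path(cfg, "map_t1"))
  for (nm in names(region$drivers)) {
    write_grid(region$drivers[[nm]], grid_path(cfg, paste0("driver_", nm)))
  }
  for (nm in setdiff(names(region$eco), "sources")) {
    write_grid(region$eco[[nm]], grid_path(cfg, paste0("eco_", nm)))
  }
  utils::write.csv(evolved$truth, file.path(cfg$out_dir, "growth_truth.csv"),
                   row.names = FALSE)
  invisible(region)
}

read_driver_stack <- function(cfg) {
  files <- list.files(cfg$out_dir, pattern = "^driver_.*\\.asc$",
                      full.names = TRUE)
  if (!length(files)) stop("no driver rasters found in ", cfg$out_dir, call. = FALSE)
  stats::setNames(
    purrr::map(files, read_grid, kind = "continuous"),
    sub("^driver_(.*)\\.asc$", "\\1", basename(files))
  )
}

stage_calibrate <- function(cfg) {
  p <- cfg$calibrate %||% list()
  t0 <- read_grid(grid_path(cfg, "map_t0"))
  t1 <- read_grid(grid_path(cfg, "map_t1"))
  drivers <- read_driver_stack(cfg)
  samples <- extract_expansion_samples(
    t0, t1, drivers, sampling_rate = p$sampling_rate %||% 0.05,
    seed = cfg$seed)
  dev <- fit_development_probability(
    samples, n_trees = p$n_trees %||% 20,
    mtry = p$mtry %||% 9, seed = cfg$seed)
  for (nm in names(dev$surfaces)) {
    write_grid(dev$surfaces[[nm]], grid_path(cfg, paste0("pdev_", nm)))
  }
  utils::write.csv(dev$importance, file.path(cfg$out_dir, "importance.csv"),
                   row.names = FALSE)
  invisible(dev)
}

stage_demand <- function(cfg) {
  p <- cfg$demand %||% list()
  tm <- if (!is.null(p$matrix_csv)) {
    read_transition_matrix(p$matrix_csv)
  } else {
    estimate_transition_matrix(read_grid(grid_path(cfg, "map_t0")),
                               read_grid(grid_path(cfg, "map_t1")))
  }
  base <- if (!is.null(p$areas_csv)) {
    tibble::as_tibble(utils::read.csv(p$areas_csv))
  } else {
    dplyr::select(class_areas(read_grid(grid_path(cfg, "map_t1"))),
                  "name", "area_ha")
  }
  if (!is.null(p$target_class)) {
    tm <- revise_transition_probability(tm, p$target_class, p$mu_j %||% 1)
  }
  projected <- project_demand(base, tm)
  utils::write.csv(projected, file.path(cfg$out_dir, "demand.csv"),
                   row.names = FALSE)
  invisible(projected)
}

stage_simulate <- function(cfg) {
  p <- cfg$simulate %||% list()
  t0 <- read_grid(grid_path(cfg, "map_t0"))
  files <- list.files(cfg$out_dir, pattern = "^pdev_.*\\.asc$",
                      full.names = TRUE)
  surfaces <- stats::setNames(
    purrr::map(files, read_grid, kind = "continuous"),
    sub("^pdev_(.*)\\.asc$", "\\1", basename(files)))
  demand <- if (!is.null(p$demand_csv)) {
    tibble::as_tibble(utils::read.csv(p$demand_csv))
  } else if (file.exists(file.path(cfg$out_dir, "demand.csv"))) {
    tibble::as_tibble(utils::read.csv(file.path(cfg$out_dir, "demand.csv")))
  } else {
    dplyr::select(class_areas(read_grid(grid_path(cfg, "map_t1"))),
                  "name", "area_ha")
  }
  config <- simulation_config(
    demand = demand, pos = p$pos %||% 0.01, delta = p$delta %||% 0.1,
    mu_k = p$mu_k %||% 0.9, step = p$step %||% 50,
    max_iterations = p$max_iterations %||% 200, seed = cfg$seed)
  sim <- simulate_landuse(t0, surfaces, config)
  write_grid(sim$map, grid_path(cfg, "map_sim"))
  utils::write.csv(sim$residuals, file.path(cfg$out_dir, "residuals.csv"),
                   row.names = FALSE)
  invisible(sim)
}

stage_validate <- function(cfg) {
  rep <- validation_report(
    read_grid(grid_path(cfg, "map_t0")),
    read_grid(grid_path(cfg, "map_t1")),
    read_grid(grid_path(cfg, "map_sim"))
  )
  jsonlite::write_json(as.list(rep), file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}

stage_indicators <- function(cfg) {
  eco_files <- list.files(cfg$out_dir, pattern = "^eco_.*\\.asc$",
                          full.names = TRUE)
  inputs <- stats::setNames(
    purrr::map(eco_files, read_grid, kind = "continuous"),
    sub("^eco_(.*)\\.asc$", "\\1", basename(eco_files)))
  map <- read_grid(grid_path(cfg, "map_t0"))
  inputs$sources <- !is.na(map$values) &
    map$values == map$class_table$code[map$class_table$name == "WT"]
  ind <- indicator_set(inputs)
  for (nm in names(ind$grades)) {
    write_grid(ind$grades[[nm]], grid_path(cfg, paste0("grade_", nm)))
    utils::write.csv(attr(ind$grades[[nm]], "breaks"),
                     file.path(cfg$out_dir, paste0("breaks_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(ind)
}

stage_risk <- function(cfg) {
  p <- cfg$risk %||% list()
  base <- read_grid(grid_path(cfg, "map_t0"))
  scen <- read_grid(grid_path(cfg, if (file.exists(grid_path(cfg, "map_sim")))
    "map_sim" else "map_t1"))
  grade_files <- list.files(cfg$out_dir, pattern = "^grade_.*\\.asc$",
                            full.names = TRUE)
  grade_ct <- tibble::tibble(
    code = 1:5, name = c("extremely_low", "low", "medium", "high",
                         "extremely_high"))
  grades <- stats::setNames(
    purrr::map(grade_files, read_grid, kind = "categorical",
               class_table = grade_ct),
    sub("^grade_(.*)\\.asc$", "\\1", basename(grade_files)))
  ra <- risk_assessment(base, scen, grades,
                        cell_side = p$cell_side %||% 600)
  utils::write.csv(ra$zones, file.path(cfg$out_dir, "risk_zones.csv"),
                   row.names = FALSE)
  utils::write.csv(ra$areas, file.path(cfg$out_dir, "risk_areas.csv"),
                   row.names = FALSE)
  write_grid(ra$map, grid_path(cfg, "risk_map"))
  invisible(ra)
}
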