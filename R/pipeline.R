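#' Run the full drone AED analysis pipeline
#'
#' Orchestrates every stage end to end: synthetic city, hourly weather and
#' OHCA cohort generation; the inclusion/exclusion cascade; the occurrence
#' and response-time risk map; genetic-algorithm station allocation; the
#' dispatch simulation for each requested scenario and pathway; and the
#' summary outcome table. One master seed drives fixed per-stage streams, so
#' a rerun with the same configuration reproduces every output exactly.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one. Recognized top-level entries (all optional): `seed` (integer),
#'   `synth` (arguments to [synth_config()]), `riskmap` (`cell_size`,
#'   `heat_radius`, `idw_power`, `idw_max_samples`), `allocation`
#'   (`k_values`, `radius`, plus [ga_params()] fields), `scenarios`
#'   (model names), `scenario_args` (extra [scenario_config()] arguments),
#'   `pathways`, `k_report` (station count used for the summary table;
#'   default the largest k), and `curves` (logical: also compute
#'   station-count curves).
#' @param out_dir optional directory; when given, the cohort and weather
#'   tables (CSV), rasters (ESRI ASCII grid), exclusion report and manifest
#'   (JSON), and summary table (CSV) are written there.
#' @return a `pipeline_run` list with the stage outputs (`city`, `weather`,
#'   `cohort`, `included`, `exclusions`, `risk`, `allocations`, `stations`,
#'   `summary`, optionally `curves`) and a reproducibility `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  scfg <- do.call(synth_config, c(list(seed = seed),
                                  config$synth %||% list()))
  rm_cfg <- config$riskmap %||% list()
  al_cfg <- config$allocation %||% list()
  models <- config$scenarios %||% c("basic", "control_advanced",
                                    "flight_advanced",
                                    "flight_control_advanced")
  pathways <- config$pathways %||% c("euclidean", "topographic")
  scenario_args <- config$scenario_args %||% list()

  city <- generate_city(scfg)
  weather <- generate_weather(scfg)
  cohort <- generate_cohort(scfg, city, weather)
  excl <- apply_exclusions(cohort)
  included <- excl$included

  cell_size <- rm_cfg$cell_size %||% 50
  lattice <- make_lattice(scfg$extent, cell_size = cell_size)
  heat <- heatmap_layer(included, lattice,
                        radius = rm_cfg$heat_radius %||% 300)
  samples <- data.frame(x = included$x, y = included$y,
                        value = included$t_scene_arrival)
  max_s <- rm_cfg$idw_max_samples %||% 2000
  if (nrow(samples) > max_s) {
    set.seed(stage_seed(scfg, 404L))
    samples <- samples[sample.int(nrow(samples), max_s), ]
  }
  response <- idw_layer(samples, lattice,
                        power = rm_cfg$idw_power %||% 2)
  risk <- combine_risk(heat, response)

  k_values <- al_cfg$k_values %||%
    unique(pmin(seq(5, scfg$n_stations + 4, by = 5), scfg$n_stations))
  gp <- ga_params(pop_size = al_cfg$pop_size %||% 50,
                  generations = al_cfg$generations %||% 200,
                  tournament = al_cfg$tournament %||% 3,
                  mutation_rate = al_cfg$mutation_rate %||% 0.1,
                  stagnation = al_cfg$stagnation %||% 40)
  allocations <- sweep_k(city$stations, risk, k_values = k_values,
                         radius = al_cfg$radius %||% 3000,
                         seed = stage_seed(scfg, 505L), params = gp)
  k_report <- config$k_report %||% max(k_values)
  idx <- match(k_report, vapply(allocations, `[[`, 0, "k"))
  if (is.na(idx)) stop("k_report must be one of the swept k values")
  al <- allocations[[idx]]
  stations <- city$stations[match(al$selected, city$stations$id), ,
                            drop = FALSE]

  summary <- outcome_summary_table(included, stations, city$grid, weather,
                                   models = models, pathways = pathways,
                                   scenario_args = scenario_args)
  curves <- NULL
  if (isTRUE(config$curves)) {
    curves <- station_count_curves(included, city$grid, weather,
                                   city$stations, allocations,
                                   models = models,
                                   pathway = pathways[length(pathways)],
                                   scenario_args = scenario_args)
  }

  manifest <- list(
    seed = seed,
    config_hash = hash_config(config),
    stage_seeds = list(city = stage_seed(scfg, 101L),
                       weather = stage_seed(scfg, 202L),
                       cohort = stage_seed(scfg, 303L),
                       idw_subsample = stage_seed(scfg, 404L),
                       allocation = stage_seed(scfg, 505L)),
    counts = list(n_cases = nrow(cohort), n_included = nrow(included),
                  n_weather_hours = nrow(weather),
                  n_candidate_stations = nrow(city$stations),
                  k_report = al$k),
    scenarios = models, pathways = pathways)

  run <- structure(list(config = config, city = city, weather = weather,
                        cohort = cohort, included = included,
                        exclusions = excl$report, risk = risk,
                        allocations = allocations, stations = stations,
                        summary = summary, curves = curves,
                        manifest = manifest),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_outputs(run, out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hash_config <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_cohort_csv(run$cohort, p("cohort.csv"))
  write_cohort_csv(run$included, p("cohort_included.csv"))
  utils::write.csv(run$weather, p("weather.csv"), row.names = FALSE)
  utils::write.csv(run$city$stations, p("stations.csv"), row.names = FALSE)
  write_exclusion_report(run$exclusions, p("exclusions.json"))
  g <- run$city$grid
  write_ascii_grid(raster_grid(g$elevation, g$origin, g$cell_size),
                   p("elevation.asc"))
  write_ascii_grid(raster_grid(g$building_height, g$origin, g$cell_size),
                   p("building_height.asc"))
  write_ascii_grid(run$risk, p("risk.asc"))
  utils::write.csv(run$summary, p("summary.csv"), row.names = FALSE)
  if (!is.null(run$curves)) {
    utils::write.csv(run$curves, p("curves.csv"), row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Drone AED delivery pipeline run\n")
  cat(sprintf("  seed %d, %d cases generated, %d included\n",
              x$manifest$seed, x$manifest$counts$n_cases,
              x$manifest$counts$n_included))
  cat(sprintf("  %d candidate stations, reporting k = %d\n",
              x$manifest$counts$n_candidate_stations,
              x$manifest$counts$k_report))
  cat("  summary:\n")
  print(x$summary[, c("scenario", "pathway", "pct_dispatched",
                      "call_to_attach", "pct_pre_arrival")])
  invisible(x)
}
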