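#' Configuration for the synthetic city, weather and cohort generators
#'
#' Bundles every knob of the synthetic-data module with defaults calibrated
#' to the metropolitan OHCA setting the simulation targets: a four-year study
#' window, hourly weather with the registry's marginal frequencies of extreme
#' conditions, and log-normal EMS time intervals parameterized by their
#' published median and interquartile range.
#'
#' @param seed master integer seed; the city, weather and cohort stages draw
#'   from fixed offsets of it so each stage is independently reproducible.
#' @param n_cases number of OHCA cases to generate.
#' @param extent city extent in metres, `c(width, height)`; must be at least
#'   1 km in each direction.
#' @param n_stations number of candidate drone stations (>= 2).
#' @param terrain_cell_size elevation raster resolution in metres.
#' @param n_hills number of Gaussian terrain hills.
#' @param hill_height maximum hill elevation (m).
#' @param building_density buildings per square kilometre.
#' @param building_height_meanlog,building_height_sdlog log-normal parameters
#'   of building heights (m).
#' @param n_hours length of the hourly weather series; the default covers
#'   2013--2016 (35,064 h including one leap year).
#' @param weather named list of regime probabilities per weather block:
#'   `rain`, `snow`, `subzero`, `low_visibility`, `strong_wind`,
#'   `lightning` (all in `[0, 1]`). Defaults are the cohort's marginal
#'   frequencies: rain 9.6%, snow 5.3%, sub-zero 16.0%, sight < 1 km 10.7%.
#' @param weather_block_hours regime persistence: consecutive hours sharing
#'   one regime draw.
#' @param intervals named list of `c(median, q25, q75)` minutes for the EMS
#'   timeline intervals `recognition` (call to arrest recognition),
#'   `ems_departure` (call to ambulance departure), `ems_response` (call to
#'   scene arrival) and `scene_to_attach` (scene arrival to AED attach).
#' @param covariates named list of Utstein covariate probabilities:
#'   `male`, `witnessed`, `bystander_cpr`, `public_location`,
#'   `unknown_location`, `shockable`, `unknown_rhythm`, `ems_defibrillation`.
#' @param exclusion_fractions named list of rates at which records receive
#'   features tripping the cohort exclusion cascade: `under8`,
#'   `in_ambulance`, `missing_attach`, `missing_recognition`.
#' @param n_clusters number of spatial clusters in the event-location
#'   mixture.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_cases = 500L,
                         extent = c(1000, 1000),
                         n_stations = 12L,
                         terrain_cell_size = 10,
                         n_hills = 4L,
                         hill_height = 60,
                         building_density = 25,
                         building_height_meanlog = log(15),
                         building_height_sdlog = 0.7,
                         n_hours = 35064L,
                         weather = list(rain = 0.096, snow = 0.053,
                                        subzero = 0.160,
                                        low_visibility = 0.107,
                                        strong_wind = 1e-4,
                                        lightning = 0.005),
                         weather_block_hours = 6L,
                         intervals = list(
                           recognition = c(2.4, 1.6, 3.4),
                           ems_departure = c(1, 0, 1),
                           ems_response = c(6, 4, 7),
                           scene_to_attach = c(2, 1, 4)),
                         covariates = list(
                           male = 0.637, witnessed = 0.430,
                           bystander_cpr = 0.450,
                           public_location = 0.226,
                           unknown_location = 0.050,
                           shockable = 0.150, unknown_rhythm = 0.008,
                           ems_defibrillation = 0.213),
                         exclusion_fractions = list(
                           under8 = 0, in_ambulance = 0,
                           missing_attach = 0, missing_recognition = 0),
                         n_clusters = 3L) {
  probs <- c(unlist(weather), unlist(covariates),
             unlist(exclusion_fractions))
  if (any(probs < 0 | probs > 1)) {
    stop("all regime, covariate and exclusion probabilities must lie in [0, 1]")
  }
  for (nm in names(intervals)) {
    iv <- intervals[[nm]]
    if (length(iv) != 3 || iv[1] <= 0 || iv[3] <= 0 || iv[3] < iv[1]) {
      stop("interval '", nm, "' needs c(median, q25, q75) with median, q75 > 0")
    }
  }
  if (length(extent) != 2 || any(extent <= 0)) {
    stop("extent must be two positive lengths in metres")
  }
  if (n_stations < 1) stop("at least one candidate station is required")
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 extent = as.numeric(extent),
                 n_stations = as.integer(n_stations),
                 terrain_cell_size = terrain_cell_size,
                 n_hills = as.integer(n_hills), hill_height = hill_height,
                 building_density = building_density,
                 building_height_meanlog = building_height_meanlog,
                 building_height_sdlog = building_height_sdlog,
                 n_hours = as.integer(n_hours), weather = weather,
                 weather_block_hours = as.integer(weather_block_hours),
                 intervals = intervals, covariates = covariates,
                 exclusion_fractions = exclusion_fractions,
                 n_clusters = as.integer(n_clusters)),
            class = "synth_config")
}

# Stage seeds: fixed offsets of the master seed, kept below 2^31.
stage_seed <- function(config, offset) {
  as.integer((abs(config$seed) + offset) %% .Machine$integer.max)
}

# Log-normal (meanlog, sdlog) matched to a reported median and IQR.
# A zero lower quartile (possible in coarsely rounded registry data) falls
# back to matching the upper quartile only; a degenerate IQR collapses to an
# (almost) constant draw.
lnorm_from_quartiles <- function(median, q25, q75) {
  meanlog <- log(median)
  sdlog <- if (q25 > 0) {
    (log(q75) - log(q25)) / (2 * stats::qnorm(0.75))
  } else {
    (log(q75) - log(median)) / stats::qnorm(0.75)
  }
  if (!is.finite(sdlog) || sdlog <= 0) sdlog <- 1e-9
  list(meanlog = meanlog, sdlog = sdlog)
}

#' Terrain grid: elevation plus building heights
#'
#' @param elevation,building_height numeric matrices of identical shape:
#'   ground altitude (m) and structure height above ground (m).
#' @param origin,cell_size lattice geometry as in [raster_grid()].
#' @return an object of class `terrain_grid`.
#' @export
terrain_grid <- function(elevation, building_height,
                         origin = c(0, 0), cell_size = 10) {
  stopifnot(identical(dim(elevation), dim(building_height)),
            all(is.finite(elevation)), all(building_height >= 0))
  structure(list(elevation = elevation, building_height = building_height,
                 origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size)),
            class = "terrain_grid")
}

#' @export
print.terrain_grid <- function(x, ...) {
  d <- dim(x$elevation)
  cat(sprintf("terrain_grid: %d x %d cells of %g m (%g x %g km)\n",
              d[1], d[2], x$cell_size,
              d[2] * x$cell_size / 1000, d[1] * x$cell_size / 1000))
  cat(sprintf("  elevation %g..%g m; %d built cells, max building %g m\n",
              round(min(x$elevation), 1), round(max(x$elevation), 1),
              sum(x$building_height > 0), round(max(x$building_height), 1)))
  invisible(x)
}

# Ground elevation (m) at planar points; errors outside the grid.
ground_elevation <- function(grid, x, y) {
  g <- raster_grid(grid$elevation, grid$origin, grid$cell_size)
  idx <- point_to_cell(g, x, y)
  grid$elevation[cbind(idx$iy, idx$ix)]
}

#' Generate a synthetic city
#'
#' Builds a smooth elevation field as a sum of seeded 2-D Gaussian hills,
#' scatters rectangular building footprints with log-normal heights, and
#' places candidate drone stations on open-ground (building-free) cells.
#' Deterministic given `config$seed`.
#'
#' @param config a [synth_config()]; requires extent of at least
#'   1 km x 1 km and at least 2 candidate stations.
#' @return list with `grid` (a [terrain_grid()]) and `stations`
#'   (data.frame `id`, `x`, `y`, `elevation`).
#' @export
generate_city <- function(config) {
  if (any(config$extent < 1000)) {
    stop("city extent must be at least 1 km x 1 km")
  }
  if (config$n_stations < 2) stop("at least 2 candidate stations are required")
  set.seed(stage_seed(config, 101L))
  cs <- config$terrain_cell_size
  nx <- ceiling(config$extent[1] / cs)
  ny <- ceiling(config$extent[2] / cs)
  xc <- (seq_len(nx) - 0.5) * cs
  yc <- (seq_len(ny) - 0.5) * cs

  elev <- matrix(0, ny, nx)
  for (i in seq_len(config$n_hills)) {
    ctr <- stats::runif(2, 0, config$extent)
    sd <- stats::runif(1, min(config$extent) / 10, min(config$extent) / 4)
    h <- stats::runif(1, 0.3, 1) * config$hill_height
    elev <- elev + h * outer(exp(-(yc - ctr[2])^2 / (2 * sd^2)),
                             exp(-(xc - ctr[1])^2 / (2 * sd^2)))
  }

  bh <- matrix(0, ny, nx)
  n_bldg <- round(config$building_density * prod(config$extent) / 1e6)
  for (i in seq_len(n_bldg)) {
    ctr <- stats::runif(2, 0, config$extent)
    half <- stats::runif(2, 5, 30)
    h <- stats::rlnorm(1, config$building_height_meanlog,
                       config$building_height_sdlog)
    ix <- max(1, floor((ctr[1] - half[1]) / cs) + 1):
          min(nx, floor((ctr[1] + half[1]) / cs) + 1)
    iy <- max(1, floor((ctr[2] - half[2]) / cs) + 1):
          min(ny, floor((ctr[2] + half[2]) / cs) + 1)
    bh[iy, ix] <- pmax(bh[iy, ix], h)
  }

  open_cells <- which(bh == 0)
  if (length(open_cells) < config$n_stations) {
    stop("not enough building-free cells to place stations")
  }
  pick <- sample(open_cells, config$n_stations)
  iy <- (pick - 1L) %% ny + 1L
  ix <- (pick - 1L) %/% ny + 1L
  stations <- data.frame(id = seq_len(config$n_stations),
                         x = xc[ix], y = yc[iy],
                         elevation = elev[cbind(iy, ix)])
  list(grid = terrain_grid(elev, bh, origin = c(0, 0), cell_size = cs),
       stations = stations)
}

#' Generate an hourly weather series
#'
#' Hours are grouped into persistence blocks; each block independently draws
#' its regimes (rain, snow, sub-zero temperature, low visibility, strong
#' wind) with the configured probabilities, and hourly values are then drawn
#' conditional on the block regime. Calm hours carry zero wind and 20 km
#' visibility, so with all probabilities zero the series is uniformly flyable.
#'
#' @param config a [synth_config()].
#' @param n_hours number of hourly records (default `config$n_hours`).
#' @return data.frame of class `weather_series` with columns `hour_index`
#'   (0-based hours from the study epoch, midnight-aligned), `wind_speed`
#'   (m/s), `precipitation` (mm/h), `snowfall` (cm/h), `temperature` (deg C),
#'   `sight_distance` (m) and `lightning` (logical).
#' @export
generate_weather <- function(config, n_hours = config$n_hours) {
  if (n_hours < 1) stop("n_hours must be >= 1")
  set.seed(stage_seed(config, 202L))
  p <- config$weather
  n_blocks <- ceiling(n_hours / config$weather_block_hours)
  blk <- rep(seq_len(n_blocks), each = config$weather_block_hours)[1:n_hours]
  draw <- function(prob) stats::runif(n_blocks) < prob
  rain <- draw(p$rain)[blk]
  snow <- draw(p$snow)[blk]
  subzero <- draw(p$subzero)[blk]
  lowvis <- draw(p$low_visibility)[blk]
  wind <- draw(p$strong_wind)[blk]

  n <- n_hours
  wx <- data.frame(
    hour_index = 0:(n - 1L),
    wind_speed = ifelse(wind, stats::runif(n, 10, 18), 0),
    precipitation = ifelse(rain, stats::runif(n, 0.2, 8), 0),
    snowfall = ifelse(snow, stats::runif(n, 0.1, 3), 0),
    temperature = ifelse(subzero, stats::runif(n, -12, -0.1),
                         stats::runif(n, 5, 25)),
    sight_distance = ifelse(lowvis, stats::runif(n, 100, 999), 20000),
    lightning = stats::runif(n) < p$lightning)
  class(wx) <- c("weather_series", "data.frame")
  wx
}

#' Generate a synthetic OHCA cohort
#'
#' Each case receives a call time uniform over the weather window, a
#' location from a spatial Gaussian-mixture (so the occurrence heat-map is
#' non-trivial), Utstein covariates, and log-normal EMS timeline intervals
#' matched to the configured medians and IQRs. A configurable fraction of
#' records receive features that trip the inclusion/exclusion cascade
#' (age under 8, arrest during ambulance transport, missing AED-attach or
#' arrest-recognition times).
#'
#' @param config a [synth_config()].
#' @param city output of [generate_city()] (used for the extent).
#' @param weather a weather series from [generate_weather()]; the call-time
#'   window is its span.
#' @param exclusion_counts optional named integer vector
#'   `c(under8 =, in_ambulance =, missing_attach =, missing_recognition =)`
#'   assigning exact, disjoint numbers of records to each exclusion feature
#'   (in cascade order) instead of the independent per-record fractions.
#' @return data.frame of class `ohca_cohort`, one row per case, with the
#'   timeline columns `t_recognition`, `t_ems_departure`, `t_scene_arrival`,
#'   `t_aed_attach` in minutes from the call and `call_time` in minutes from
#'   the study epoch.
#' @export
generate_cohort <- function(config, city, weather,
                            exclusion_counts = NULL) {
  set.seed(stage_seed(config, 303L))
  n <- config$n_cases
  cols <- c("id", "age", "gender", "witnessed", "location_type",
            "bystander_cpr", "initial_rhythm", "ems_defibrillation",
            "call_time", "x", "y", "in_ambulance_arrest", "t_recognition",
            "t_ems_departure", "t_scene_arrival", "t_aed_attach")
  if (n == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    class(out) <- c("ohca_cohort", "data.frame")
    return(out)
  }
  n_hours <- max(weather$hour_index) + 1L
  ext <- config$extent

  call_time <- stats::runif(n, 0, n_hours * 60)
  k <- config$n_clusters
  ctrs <- cbind(stats::runif(k, 0.1, 0.9) * ext[1],
                stats::runif(k, 0.1, 0.9) * ext[2])
  grp <- sample.int(k, n, replace = TRUE)
  sdc <- min(ext) / 8
  eps <- 1e-6
  x <- pmin(pmax(stats::rnorm(n, ctrs[grp, 1], sdc), 0), ext[1] - eps)
  y <- pmin(pmax(stats::rnorm(n, ctrs[grp, 2], sdc), 0), ext[2] - eps)

  cv <- config$covariates
  age <- pmin(pmax(stats::rnorm(n, 66, 18), 9), 100)
  gender <- ifelse(stats::runif(n) < cv$male, "male", "female")
  loc_u <- stats::runif(n)
  location_type <- ifelse(loc_u < cv$public_location, "public",
                          ifelse(loc_u < cv$public_location +
                                   cv$unknown_location, "unknown", "private"))
  rhy_u <- stats::runif(n)
  initial_rhythm <- ifelse(rhy_u < cv$shockable, "shockable",
                           ifelse(rhy_u < cv$shockable + cv$unknown_rhythm,
                                  "unknown", "non-shockable"))

  pars <- lapply(config$intervals, function(iv)
    lnorm_from_quartiles(iv[1], iv[2], iv[3]))
  rln <- function(p) stats::rlnorm(n, p$meanlog, p$sdlog)
  t_recognition <- rln(pars$recognition)
  t_scene_arrival <- rln(pars$ems_response)
  t_ems_departure <- pmin(rln(pars$ems_departure), t_scene_arrival)
  t_aed_attach <- t_scene_arrival + rln(pars$scene_to_attach)

  in_ambulance <- rep(FALSE, n)
  miss_attach <- rep(FALSE, n)
  miss_recog <- rep(FALSE, n)
  if (!is.null(exclusion_counts)) {
    ec <- exclusion_counts
    need <- sum(ec)
    if (need > n) stop("exclusion_counts exceed n_cases")
    pool <- sample.int(n, need)
    take <- function(m) {
      out <- pool[seq_len(m)]
      pool <<- pool[-seq_len(m)]
      out
    }
    if (ec[["under8"]] > 0) {
      i <- take(ec[["under8"]])
      age[i] <- stats::runif(length(i), 0, 7.99)
    }
    if (ec[["in_ambulance"]] > 0) in_ambulance[take(ec[["in_ambulance"]])] <- TRUE
    if (ec[["missing_attach"]] > 0) miss_attach[take(ec[["missing_attach"]])] <- TRUE
    if (ec[["missing_recognition"]] > 0) {
      miss_recog[take(ec[["missing_recognition"]])] <- TRUE
    }
  } else {
    ef <- config$exclusion_fractions
    under8 <- stats::runif(n) < ef$under8
    age[under8] <- stats::runif(sum(under8), 0, 7.99)
    in_ambulance <- stats::runif(n) < ef$in_ambulance
    miss_attach <- stats::runif(n) < ef$missing_attach
    miss_recog <- stats::runif(n) < ef$missing_recognition
  }
  t_aed_attach[miss_attach] <- NA_real_
  t_recognition[miss_recog] <- NA_real_

  out <- data.frame(
    id = seq_len(n), age = age, gender = gender,
    witnessed = stats::runif(n) < cv$witnessed,
    location_type = location_type,
    bystander_cpr = stats::runif(n) < cv$bystander_cpr,
    initial_rhythm = initial_rhythm,
    ems_defibrillation = stats::runif(n) < cv$ems_defibrillation,
    call_time = call_time, x = x, y = y,
    in_ambulance_arrest = in_ambulance,
    t_recognition = t_recognition, t_ems_departure = t_ems_departure,
    t_scene_arrival = t_scene_arrival, t_aed_attach = t_aed_attach)
  class(out) <- c("ohca_cohort", "data.frame")
  out
}
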