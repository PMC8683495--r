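#' Drone scenario configuration
#'
#' The four drone capability scenarios differ only in which launch gates
#' apply: the basic model is grounded by extreme weather (strong wind, rain,
#' snow, sub-zero temperature) and by poor visibility (nighttime or sight
#' distance under 1 km); the control-advanced model ignores visibility; the
#' flight-advanced model ignores weather; the flight-and-control-advanced
#' model always launches.
#'
#' @param model one of `"basic"`, `"control_advanced"`, `"flight_advanced"`,
#'   `"flight_control_advanced"`.
#' @param wind_limit wind speed at or above which weather is extreme (m/s;
#'   default 10).
#' @param temp_limit temperature below which weather is extreme (deg C).
#' @param night_start,night_end clock hours bounding nighttime (default
#'   18:00--06:00).
#' @param sight_limit sight distance below which visibility is poor (m).
#' @param max_dispatch_range maximum station-to-scene ground distance for a
#'   launch (m; default 3000, matching the siting coverage radius).
#' @param attach_delay minutes from drone arrival to AED attachment.
#' @param turnaround extra minutes a drone is unavailable after returning.
#' @param lightning_blocks treat a lightning hour as extreme weather
#'   (default `FALSE`; the published gate list omits it).
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(model = c("basic", "control_advanced",
                                      "flight_advanced",
                                      "flight_control_advanced"),
                            wind_limit = 10, temp_limit = 0,
                            night_start = 18, night_end = 6,
                            sight_limit = 1000, max_dispatch_range = 3000,
                            attach_delay = 2, turnaround = 0,
                            lightning_blocks = FALSE) {
  model <- match.arg(model)
  stopifnot(wind_limit > 0, sight_limit > 0, max_dispatch_range > 0,
            attach_delay >= 0, turnaround >= 0)
  structure(list(model = model, wind_limit = wind_limit,
                 temp_limit = temp_limit, night_start = night_start,
                 night_end = night_end, sight_limit = sight_limit,
                 max_dispatch_range = max_dispatch_range,
                 attach_delay = attach_delay, turnaround = turnaround,
                 lightning_blocks = lightning_blocks),
            class = "scenario_config")
}

#' Weather and visibility launch gate
#'
#' Evaluates the scenario's launch rule against the weather record of the
#' hour in which the call was received.
#'
#' @param record one row of a weather series (see [generate_weather()]).
#' @param is_night was the call received at night (18:00--06:00)?
#' @param scenario a [scenario_config()].
#' @return list with `allowed` (logical) and `reasons` (character subset of
#'   `"weather"`, `"visibility"`; empty when allowed).
#' @export
weather_gate <- function(record, is_night, scenario) {
  if (nrow(record) != 1 || any(is.na(record))) {
    stop("weather_gate needs the single, complete record of the call hour")
  }
  extreme <- record$wind_speed >= scenario$wind_limit ||
    record$precipitation > 0 || record$snowfall > 0 ||
    record$temperature < scenario$temp_limit ||
    (scenario$lightning_blocks && record$lightning)
  poor_vis <- is_night || record$sight_distance < scenario$sight_limit
  reasons <- character(0)
  blocked_weather <- extreme &&
    scenario$model %in% c("basic", "control_advanced")
  blocked_vis <- poor_vis &&
    scenario$model %in% c("basic", "flight_advanced")
  if (blocked_weather) reasons <- c(reasons, "weather")
  if (blocked_vis) reasons <- c(reasons, "visibility")
  list(allowed = length(reasons) == 0, reasons = reasons)
}

# Clock-hour nighttime rule (fixed 18:00/06:00 boundaries by default).
is_night_hour <- function(hour_of_day, scenario) {
  hour_of_day >= scenario$night_start | hour_of_day < scenario$night_end
}

#' Nearest station with an available drone
#'
#' Among stations within dispatch range whose drone is free at the dispatch
#' time, returns the one at minimum ground distance; ties break on station
#' id.
#'
#' @param case_xy numeric `c(x, y)` of the scene (m).
#' @param stations data.frame `id`, `x`, `y` of operating stations.
#' @param busy_until numeric vector (minutes from epoch), parallel to
#'   `stations`: when each drone next becomes available.
#' @param t_dispatch dispatch time (minutes from epoch).
#' @param max_range maximum dispatch distance (m).
#' @return list with `station` (row index into `stations`, or `NA`),
#'   `distance` (m) and `reason` (`NA`, `"no_station_in_range"` or
#'   `"drone_busy"`).
#' @export
nearest_available_station <- function(case_xy, stations, busy_until,
                                      t_dispatch, max_range = 3000) {
  if (nrow(stations) == 0) {
    return(list(station = NA_integer_, distance = NA_real_,
                reason = "no_station_in_range"))
  }
  d <- sqrt((stations$x - case_xy[1])^2 + (stations$y - case_xy[2])^2)
  in_range <- d <= max_range
  if (!any(in_range)) {
    return(list(station = NA_integer_, distance = NA_real_,
                reason = "no_station_in_range"))
  }
  free <- in_range & busy_until <= t_dispatch
  if (!any(free)) {
    return(list(station = NA_integer_, distance = NA_real_,
                reason = "drone_busy"))
  }
  ord <- order(!free, d, stations$id)
  i <- ord[1]
  list(station = i, distance = d[i], reason = NA_character_)
}

#' Simulate the drone AED program over a cohort
#'
#' Processes the included cohort in call-time order. For each case the drone
#' is dispatched at arrest recognition; launch requires the scenario's
#' weather/visibility gate to pass and a free drone within dispatch range
#' (one drone per station, busy from dispatch until return, i.e. twice the
#' flight time plus turnaround). Flight time follows the chosen pathway:
#' straight-line cruise (`"euclidean"`) or climb-cruise-descend block path
#' (`"topographic"`).
#'
#' @param cohort an included `ohca_cohort` (after [apply_exclusions()]).
#' @param stations operating stations (`id`, `x`, `y`).
#' @param grid a [terrain_grid()] (used by the topographic pathway).
#' @param weather a `weather_series` covering every call hour.
#' @param scenario a [scenario_config()].
#' @param pathway `"euclidean"` or `"topographic"`.
#' @param db traversal database for the topographic pathway.
#' @return data.frame of class `dispatch_results`, one row per case (in
#'   call-time order): `case_id`, `dispatched`, `blocked_reasons`
#'   (semicolon-joined, `""` when dispatched), `station_id`, `flight_time`
#'   (min) and `uav_attach_time` (min from call; `NA` unless dispatched).
#' @export
simulate_program <- function(cohort, stations, grid, weather, scenario,
                             pathway = c("euclidean", "topographic"),
                             db = default_traversal_db()) {
  pathway <- match.arg(pathway)
  ord <- order(cohort$call_time)
  cohort <- cohort[ord, , drop = FALSE]
  n <- nrow(cohort)
  busy_until <- rep(-Inf, nrow(stations))
  out <- data.frame(case_id = cohort$id, dispatched = logical(n),
                    blocked_reasons = character(n),
                    station_id = rep(NA_integer_, n),
                    flight_time = rep(NA_real_, n),
                    uav_attach_time = rep(NA_real_, n))
  if (n == 0) {
    class(out) <- c("dispatch_results", "data.frame")
    return(out)
  }
  wx_index <- match(floor(cohort$call_time / 60), weather$hour_index)
  if (any(is.na(wx_index))) {
    stop("weather series does not cover every call hour")
  }
  for (i in seq_len(n)) {
    hour_of_day <- floor(cohort$call_time[i] / 60) %% 24
    gate <- weather_gate(weather[wx_index[i], , drop = FALSE],
                         is_night_hour(hour_of_day, scenario), scenario)
    reasons <- gate$reasons
    if (gate$allowed) {
      t_dispatch <- cohort$call_time[i] + cohort$t_recognition[i]
      found <- nearest_available_station(
        c(cohort$x[i], cohort$y[i]), stations, busy_until, t_dispatch,
        max_range = scenario$max_dispatch_range)
      if (is.na(found$station)) {
        reasons <- c(reasons, found$reason)
      } else {
        st <- found$station
        ft <- if (pathway == "euclidean") {
          euclidean_flight_time(found$distance)
        } else {
          topographic_flight_time(grid,
                                  c(stations$x[st], stations$y[st]),
                                  c(cohort$x[i], cohort$y[i]), db = db)
        }
        out$dispatched[i] <- TRUE
        out$station_id[i] <- stations$id[st]
        out$flight_time[i] <- ft
        out$uav_attach_time[i] <- cohort$t_recognition[i] + ft +
          scenario$attach_delay
        busy_until[st] <- t_dispatch + 2 * ft + scenario$turnaround
      }
    }
    out$blocked_reasons[i] <- paste(reasons, collapse = ";")
  }
  class(out) <- c("dispatch_results", "data.frame")
  out
}
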