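# In-code fixtures shared across the suite.

# Flat terrain of the given extent (m) with optional buildings, a list of
# list(x =, y =, h =) placed on single cells.
flat_grid <- function(extent = c(1000, 1000), cell = 10, elev = 0,
                      buildings = list()) {
  nx <- ceiling(extent[1] / cell)
  ny <- ceiling(extent[2] / cell)
  e <- matrix(elev, ny, nx)
  b <- matrix(0, ny, nx)
  for (bl in buildings) {
    ix <- floor(bl$x / cell) + 1
    iy <- floor(bl$y / cell) + 1
    b[iy, ix] <- bl$h
  }
  terrain_grid(e, b, origin = c(0, 0), cell_size = cell)
}

# A clear, warm, daytime-safe weather series of n hours.
clear_weather <- function(n_hours = 24) {
  wx <- data.frame(hour_index = 0:(n_hours - 1), wind_speed = 0,
                   precipitation = 0, snowfall = 0, temperature = 15,
                   sight_distance = 20000, lightning = FALSE)
  class(wx) <- c("weather_series", "data.frame")
  wx
}

# Minimal cohort row(s) for the dispatch simulation.
mini_cohort <- function(x, y, call_time, t_recognition,
                        t_aed_attach = 10, t_scene_arrival = 8) {
  n <- max(length(x), length(call_time))
  out <- data.frame(id = seq_len(n), age = 60, gender = "male",
                    witnessed = TRUE, location_type = "public",
                    bystander_cpr = FALSE, initial_rhythm = "shockable",
                    ems_defibrillation = FALSE, call_time = call_time,
                    x = x, y = y, in_ambulance_arrest = FALSE,
                    t_recognition = t_recognition,
                    t_ems_departure = 1, t_scene_arrival = t_scene_arrival,
                    t_aed_attach = t_aed_attach)
  class(out) <- c("ohca_cohort", "data.frame")
  out
}

# Direct quartic kernel sum at a point (heat-map oracle).
quartic_sum <- function(px, py, events, radius = 300) {
  d <- sqrt((events$x - px)^2 + (events$y - py)^2)
  sum(((1 - (d / radius)^2)^2)[d <= radius])
}

# Direct inverse-distance-weighted mean at a point (IDW oracle).
idw_point <- function(px, py, samples, power = 2) {
  d <- sqrt((samples$x - px)^2 + (samples$y - py)^2)
  w <- d^(-power)
  sum(w * samples$value) / sum(w)
}

# Exact two-sided signed-rank p-value by enumerating all sign assignments.
signed_rank_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(stats_all <= obs), mean(stats_all >= obs))
  min(p, 1)
}

# Best coverage over all k-subsets by exhaustive enumeration (GA oracle).
exhaustive_best <- function(stations, k, risk, radius = 3000) {
  combos <- utils::combn(stations$id, k)
  max(apply(combos, 2, coverage_score, risk = risk, stations = stations,
            radius = radius))
}

# A seeded random risk map on a small lattice.
random_risk <- function(extent = c(1500, 1500), cell = 100, seed = 1) {
  set.seed(seed)
  lat <- make_lattice(extent, cell_size = cell)
  vals <- matrix(stats::runif(prod(dim(lat$values))), nrow(lat$values))
  out <- raster_grid(vals, lat$origin, lat$cell_size)
  class(out) <- c("risk_map", class(out))
  out
}

# Seeded random candidate stations inside an extent.
random_stations <- function(n, extent = c(1500, 1500), seed = 1) {
  set.seed(seed)
  data.frame(id = seq_len(n), x = stats::runif(n, 0, extent[1]),
             y = stats::runif(n, 0, extent[2]))
}
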