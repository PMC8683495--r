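wx_row <- function(wind = 0, precip = 0, snow = 0, temp = 15,
                   sight = 20000, lightning = FALSE) {
  data.frame(hour_index = 0, wind_speed = wind, precipitation = precip,
             snowfall = snow, temperature = temp, sight_distance = sight,
             lightning = lightning)
}

models <- c("basic", "control_advanced", "flight_advanced",
            "flight_control_advanced")

test_that("the launch gate reproduces the scenario truth table", {
  # rows: (extreme weather?, poor visibility?); expected allowed per model
  conditions <- list(
    clear_day = list(wx = wx_row(), night = FALSE,
                     allowed = c(TRUE, TRUE, TRUE, TRUE)),
    extreme_day = list(wx = wx_row(temp = -1), night = FALSE,
                       allowed = c(FALSE, FALSE, TRUE, TRUE)),
    clear_night = list(wx = wx_row(), night = TRUE,
                       allowed = c(FALSE, TRUE, FALSE, TRUE)),
    extreme_night = list(wx = wx_row(precip = 2), night = TRUE,
                         allowed = c(FALSE, FALSE, FALSE, TRUE)))
  for (cond in conditions) {
    for (i in seq_along(models)) {
      gate <- weather_gate(cond$wx, cond$night, scenario_config(models[i]))
      expect_identical(gate$allowed, cond$allowed[i])
      expect_identical(length(gate$reasons) == 0, cond$allowed[i])
    }
  }
})

test_that("each extreme-weather trigger and the visibility rules gate launches", {
  basic <- scenario_config("basic")
  for (wx in list(wx_row(wind = 10), wx_row(precip = 0.1),
                  wx_row(snow = 0.5), wx_row(temp = -0.1))) {
    g <- weather_gate(wx, FALSE, basic)
    expect_false(g$allowed)
    expect_identical(g$reasons, "weather")
  }
  fog <- weather_gate(wx_row(sight = 999), FALSE, basic)
  expect_identical(fog$reasons, "visibility")
  # lightning only gates when configured
  expect_true(weather_gate(wx_row(lightning = TRUE), FALSE, basic)$allowed)
  expect_false(weather_gate(wx_row(lightning = TRUE), FALSE,
                            scenario_config("basic",
                                            lightning_blocks = TRUE))$allowed)
  # boundary: wind below / at the limit
  expect_true(weather_gate(wx_row(wind = 9.9), FALSE, basic)$allowed)
  expect_false(weather_gate(wx_row(wind = 10), FALSE, basic)$allowed)
})

test_that("nearest available station honours distance, availability and range", {
  st <- data.frame(id = 1:2, x = c(500, 900), y = c(0, 0))
  free <- c(-Inf, -Inf)
  pick <- nearest_available_station(c(0, 0), st, free, 10)
  expect_equal(pick$station, 1)
  # nearest busy, second free
  pick2 <- nearest_available_station(c(0, 0), st, c(100, -Inf), 10)
  expect_equal(pick2$station, 2)
  # both busy
  pick3 <- nearest_available_station(c(0, 0), st, c(100, 100), 10)
  expect_true(is.na(pick3$station))
  expect_equal(pick3$reason, "drone_busy")
  # out of range
  pick4 <- nearest_available_station(c(0, 5000), st, free, 10)
  expect_equal(pick4$reason, "no_station_in_range")
  # distance ties break on station id
  tie <- data.frame(id = c(7L, 3L), x = c(100, -100), y = c(0, 0))
  expect_equal(tie$id[nearest_available_station(c(0, 0), tie,
                                                c(-Inf, -Inf), 10)$station],
               3L)
})

test_that("the worked dispatch example yields a 6.33 min drone attach time", {
  grid <- flat_grid(c(1200, 200))
  st <- data.frame(id = 1L, x = 55, y = 105)
  coh <- mini_cohort(x = 1123, y = 105, call_time = 600,
                     t_recognition = 3.05)
  res <- simulate_program(coh, st, grid, clear_weather(24),
                          scenario_config("basic"), "euclidean")
  expect_true(res$dispatched)
  expect_equal(res$flight_time, 1.28)
  expect_equal(res$uav_attach_time, 3.05 + 1.28 + 2)
})

test_that("extreme weather everywhere grounds the basic model entirely", {
  grid <- flat_grid(c(1200, 200))
  st <- data.frame(id = 1L, x = 55, y = 105)
  storm <- clear_weather(24)
  storm$precipitation <- 5
  coh <- mini_cohort(x = rep(600, 5), y = 105,
                     call_time = c(60, 300, 600, 900, 1200),
                     t_recognition = 2)
  res <- simulate_program(coh, st, grid, storm, scenario_config("basic"),
                          "euclidean")
  expect_equal(sum(res$dispatched), 0)
  expect_true(all(res$blocked_reasons != ""))
  all_go <- simulate_program(coh, st, grid, storm,
                             scenario_config("flight_control_advanced"),
                             "euclidean")
  expect_equal(sum(all_go$dispatched), 5)
})

test_that("fleet contention makes a drone unavailable until it returns", {
  grid <- flat_grid(c(1200, 200))
  st <- data.frame(id = 1L, x = 55, y = 105)
  # two calls 1 min apart; round trip of the first far exceeds the gap
  coh <- mini_cohort(x = c(1123, 1123), y = 105, call_time = c(600, 601),
                     t_recognition = 0.5)
  res <- simulate_program(coh, st, grid, clear_weather(24),
                          scenario_config("basic"), "euclidean")
  expect_identical(res$dispatched, c(TRUE, FALSE))
  expect_equal(res$blocked_reasons[2], "drone_busy")
  # a drone is never assigned to overlapping missions
  busy_from <- coh$call_time[1] + coh$t_recognition[1]
  busy_to <- busy_from + 2 * res$flight_time[1]
  expect_gt(busy_to, coh$call_time[2] + coh$t_recognition[2])
})

test_that("dispatch sets nest with scenario permissiveness on synthetic cases", {
  cfg <- synth_config(seed = 55, n_cases = 200, n_hours = 8760,
                      n_stations = 12)
  city <- generate_city(cfg)
  wx <- generate_weather(cfg, 8760)
  coh <- generate_cohort(cfg, city, wx)
  sets <- lapply(models, function(m) {
    r <- simulate_program(coh, city$stations, city$grid, wx,
                          scenario_config(m), "euclidean")
    r$case_id[r$dispatched]
  })
  names(sets) <- models
  expect_true(all(sets$basic %in% sets$control_advanced))
  expect_true(all(sets$basic %in% sets$flight_advanced))
  expect_true(all(sets$control_advanced %in% sets$flight_control_advanced))
  expect_true(all(sets$flight_advanced %in% sets$flight_control_advanced))
  # gate nesting is strict here: the permissive model dispatches more
  expect_gt(length(sets$flight_control_advanced), length(sets$basic))
})

test_that("topographic attach times dominate Euclidean ones case by case", {
  cfg <- synth_config(seed = 56, n_cases = 60, n_hours = 2000)
  city <- generate_city(cfg)
  wx <- generate_weather(cfg, 2000)
  coh <- generate_cohort(cfg, city, wx)
  sc <- scenario_config("flight_control_advanced")
  eu <- simulate_program(coh, city$stations, city$grid, wx, sc, "euclidean")
  to <- simulate_program(coh, city$stations, city$grid, wx, sc,
                         "topographic")
  both <- eu$dispatched & to$dispatched &
    eu$station_id == to$station_id
  expect_gt(sum(both), 0)
  expect_true(all(to$uav_attach_time[both] >= eu$uav_attach_time[both]))
})
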