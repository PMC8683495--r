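dispatch_row <- function(case_id, dispatched, uav = NA_real_) {
  data.frame(case_id = case_id, dispatched = dispatched,
             blocked_reasons = ifelse(dispatched, "", "weather"),
             station_id = ifelse(dispatched, 1L, NA_integer_),
             flight_time = ifelse(dispatched, 1.28, NA_real_),
             uav_attach_time = uav)
}

test_that("outcome rows follow the first-AED-to-arrive rule", {
  # ground EMS: 1 min dispatch + 7 min travel + 2 min attach = 10 min
  coh <- mini_cohort(x = 0, y = 0, call_time = 0, t_recognition = 3.05,
                     t_scene_arrival = 8, t_aed_attach = 1 + 7 + 2)
  oc <- assemble_outcomes(coh, dispatch_row(1, TRUE, uav = 6.33))
  expect_equal(oc$ems_attach, 10)
  expect_equal(oc$program_attach, 6.33)
  expect_true(oc$pre_arrival)
  expect_true(oc$within10)
  expect_false(oc$within5)

  # a non-dispatched case keeps the EMS attach time
  oc2 <- assemble_outcomes(coh, dispatch_row(1, FALSE))
  expect_equal(oc2$program_attach, 10)
  expect_false(oc2$pre_arrival)

  # a slow drone never worsens the outcome
  oc3 <- assemble_outcomes(coh, dispatch_row(1, TRUE, uav = 14))
  expect_equal(oc3$program_attach, 10)
  expect_false(oc3$pre_arrival)
  expect_error(assemble_outcomes(coh, dispatch_row(2, TRUE, 5)),
               "dispatch result")
})

test_that("program outcomes dominate EMS case-wise with nested thresholds", {
  cfg <- synth_config(seed = 61, n_cases = 150, n_hours = 2000)
  city <- generate_city(cfg)
  wx <- generate_weather(cfg, 2000)
  coh <- generate_cohort(cfg, city, wx)
  dr <- simulate_program(coh, city$stations, city$grid, wx,
                         scenario_config("flight_control_advanced"),
                         "euclidean")
  oc <- assemble_outcomes(coh, dr)
  expect_true(all(oc$program_attach <= oc$ems_attach))
  expect_true(all(oc$within10[oc$within5]))
  expect_true(all(oc$dispatched[oc$pre_arrival]))
})

test_that("the paired time test matches exact signed-rank enumeration", {
  set.seed(62)
  x <- round(runif(9, 4, 9), 2)
  y <- round(x + rnorm(9, 0.4, 0.8), 3)
  expect_equal(paired_time_test(x, y), signed_rank_exact_p(x - y),
               tolerance = 1e-12)
  # identical vectors and degenerate inputs
  expect_equal(paired_time_test(x, x), 1)
  expect_error(paired_time_test(numeric(0), numeric(0)), "no observations")
  expect_error(paired_time_test(1:3, 1:2), "equal length")
  # a uniform 1 min improvement over 100 cases is overwhelming evidence
  z <- runif(100, 5, 12)
  expect_lt(paired_time_test(z - 1, z), 0.001)
})

test_that("the paired proportion test uses exact and corrected branches", {
  expect_equal(paired_proportion_test(c(TRUE, FALSE), c(TRUE, FALSE)), 1)
  # (10, 0) discordance: exact binomial 2 * 0.5^10
  before <- rep(c(TRUE, FALSE), c(10, 5))
  after <- rep(FALSE, 15)
  before_only <- before & !after
  expect_equal(sum(before_only), 10)
  expect_equal(paired_proportion_test(before, after), 2 * 0.5^10,
               tolerance = 1e-12)
  # symmetric discordance is null-consistent
  b2 <- rep(c(TRUE, FALSE), 15)
  a2 <- rep(c(FALSE, TRUE), 15)
  expect_gt(paired_proportion_test(b2, a2), 0.8)
  # large-sample branch agrees with the continuity-corrected chi-square
  b3 <- rep(c(TRUE, FALSE, FALSE), c(30, 10, 60))
  a3 <- rep(c(FALSE, TRUE, FALSE), c(30, 10, 60))
  expect_equal(paired_proportion_test(b3, a3),
               stats::mcnemar.test(matrix(c(0, 30, 10, 0), 2, 2))$p.value)
})

test_that("summary rows count dispatches, successes and pre-arrivals", {
  coh <- mini_cohort(x = c(0, 0, 0), y = 0, call_time = c(0, 10, 20),
                     t_recognition = 2, t_aed_attach = c(10, 4, 12))
  dr <- dispatch_row(1:3, c(TRUE, FALSE, TRUE), uav = c(6, NA, 4.5))
  oc <- assemble_outcomes(coh, dr)
  s <- summarize_outcomes(oc, dr, "demo", "euclidean")
  expect_equal(s$n, 3)
  expect_equal(s$n_dispatched, 2)
  expect_equal(s$n_pre_arrival, 2)
  expect_equal(s$n_within5, 2)     # 4 (EMS) and 4.5 (drone)
  expect_equal(s$n_within10, 3)
  expect_equal(s$median_call_to_attach, 4.5)
})

test_that("station-count curves fall with k and favour the Euclidean pathway", {
  cfg <- synth_config(seed = 63, n_cases = 150, n_hours = 2000,
                      n_stations = 8)
  city <- generate_city(cfg)
  wx <- generate_weather(cfg, 2000)
  coh <- generate_cohort(cfg, city, wx)
  lat <- make_lattice(cfg$extent)
  risk <- combine_risk(
    heatmap_layer(coh, lat),
    idw_layer(data.frame(x = coh$x, y = coh$y, value = coh$t_scene_arrival),
              lat))
  allocs <- sweep_k(city$stations, risk, k_values = c(2, 4, 6, 8),
                    radius = 800, seed = 9)
  none <- structure(list(k = 0, selected = integer(0), coverage_score = 0,
                         ga_seed = 0L, generations_run = 0L),
                    class = "allocation_result")
  curves <- station_count_curves(coh, city$grid, wx, city$stations,
                                 c(list(none), allocs),
                                 models = "flight_control_advanced",
                                 pathway = "topographic")
  # no stations reproduces the EMS-only median
  expect_equal(curves$median_call_to_attach[curves$k == 0],
               median(coh$t_aed_attach))
  # medians never increase as stations are added (warm-started allocations)
  m <- curves$median_call_to_attach[order(curves$k)]
  expect_true(all(diff(m) <= 1e-9))
  # the Euclidean pathway is at least as fast pointwise
  eu <- station_count_curves(coh, city$grid, wx, city$stations,
                             c(list(none), allocs),
                             models = "flight_control_advanced",
                             pathway = "euclidean")
  expect_true(all(eu$median_call_to_attach <=
                    curves$median_call_to_attach + 1e-9))
})
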