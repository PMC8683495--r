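test_that("Euclidean flight time is distance over cruise speed, in minutes", {
  expect_equal(euclidean_flight_time(1068), 1.28)
  expect_equal(euclidean_flight_time(0), 0)
  expect_equal(euclidean_flight_time(833.33), 1.00)
  expect_error(euclidean_flight_time(-1), "non-negative")
  expect_error(euclidean_flight_time(100, 0), "positive")
})

test_that("corridor scan finds the tallest obstacle and ignores off-route ones", {
  flat <- flat_grid(c(1200, 200))
  expect_equal(corridor_max_altitude(flat, c(50, 100), c(1150, 100)), 0)

  on_route <- flat_grid(c(1200, 200),
                        buildings = list(list(x = 605, y = 105, h = 33)))
  expect_equal(corridor_max_altitude(on_route, c(50, 105), c(1150, 105)), 33)

  # a 5 x 5 hand-built grid: obstacle two cells (20 m) off the corridor
  off <- flat_grid(c(50, 50), buildings = list(list(x = 25, y = 45, h = 40)))
  expect_equal(corridor_max_altitude(off, c(5, 25), c(45, 25)), 0)
  expect_error(corridor_max_altitude(off, c(5, 25), c(60, 25)), "outside")
})

test_that("topographic plans decompose into the expected block counts", {
  # flat terrain, 33 m obstacle on route, 1068 m leg, 10 m clearance:
  # cruise at 43 m, ceil(43/10) = 5 climb and descent blocks, 107 cruise
  grid <- flat_grid(c(1200, 200),
                    buildings = list(list(x = 605, y = 105, h = 33)))
  plan <- plan_topographic_path(grid, c(55, 105), c(1123, 105))
  expect_equal(plan$cruise_altitude, 43)
  expect_equal(plan$n_climb, 5)
  expect_equal(plan$n_cruise, 107)
  expect_equal(plan$n_descent, 5)
  expect_equal(nrow(plan$blocks), 117)
  # first climb block starts from standstill; final descent block stops
  expect_equal(plan$blocks$entry_speed[1], 0)
  expect_equal(plan$blocks$escape_speed[117], 0)
  # direction changes at the two corners, nowhere else
  expect_equal(plan$blocks$escape_dir[5], "forward")
  expect_equal(plan$blocks$escape_dir[112], "down")
  expect_equal(unique(plan$blocks$entry_dir), c("up", "forward", "down"))

  # an obstacle-free city needs only the clearance climb
  open <- flat_grid(c(1200, 200))
  p2 <- plan_topographic_path(open, c(55, 105), c(1123, 105))
  expect_equal(p2$n_climb, 1)
  expect_equal(p2$n_descent, 1)
  expect_equal(p2$n_cruise, 107)

  # degenerate: station and site coincide
  p3 <- plan_topographic_path(open, c(55, 105), c(55, 105))
  expect_equal(p3$n_cruise, 0)
  expect_equal(p3$n_climb, 1)
  expect_equal(p3$n_descent, 1)
})

test_that("plan block counts are symmetric in station and site on flat terrain", {
  grid <- flat_grid(c(1200, 200),
                    buildings = list(list(x = 305, y = 105, h = 21)))
  a <- c(55, 105); b <- c(1123, 105)
  p1 <- plan_topographic_path(grid, a, b)
  p2 <- plan_topographic_path(grid, b, a)
  expect_equal(p1$n_climb, p2$n_climb)
  expect_equal(p1$n_cruise, p2$n_cruise)
  expect_equal(p1$n_descent, p2$n_descent)
})

test_that("block traversal uses the measured database with analytic fallback", {
  db <- default_traversal_db()
  # the bench-measured entry: 10 km/h down-entry, 10 km/h right-escape
  measured <- data.frame(entry_speed = 10, entry_dir = "down",
                         escape_speed = 10, escape_dir = "right")
  expect_equal(block_path_time(measured, db) * 60, 3.25)
  # analytic fallback: full-speed straight block
  straight <- data.frame(entry_speed = 50, entry_dir = "forward",
                         escape_speed = 50, escape_dir = "forward")
  expect_equal(block_path_time(straight, db) * 60, 0.72)
  # summation over a 107-block cruise at constant 50 km/h
  cruise <- straight[rep(1, 107), ]
  expect_equal(block_path_time(cruise, db) * 60, 107 * 0.72)
  expect_equal(block_path_time(straight[0, ], db), 0)
})

test_that("a user-supplied traversal table overrides the fallback", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(entry_speed = 50, entry_dir = "forward",
                       escape_speed = 50, escape_dir = "forward",
                       seconds = 1.5), path, row.names = FALSE)
  db <- read_traversal_db(path)
  straight <- data.frame(entry_speed = 50, entry_dir = "forward",
                         escape_speed = 50, escape_dir = "forward")
  expect_equal(block_path_time(straight, db) * 60, 1.5)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(entry_speed = 10, entry_dir = "sideways",
                       escape_speed = 10, escape_dir = "up", seconds = 1),
            bad, row.names = FALSE)
  expect_error(read_traversal_db(bad))
})

test_that("topographic time dominates Euclidean time and grows with obstacles", {
  open <- flat_grid(c(1200, 200))
  a <- c(55, 105); b <- c(1123, 105)
  d <- sqrt(sum((b - a)^2))
  expect_gte(topographic_flight_time(open, a, b), euclidean_flight_time(d))
  # monotone in corridor obstacle height
  times <- vapply(c(0, 15, 35, 80), function(h) {
    g <- flat_grid(c(1200, 200),
                   buildings = if (h > 0) list(list(x = 605, y = 105, h = h))
                   else list())
    topographic_flight_time(g, a, b)
  }, 0)
  expect_true(all(diff(times) >= 0))
  # zero-distance, zero-obstacle plan: clearance climb plus descent only
  p <- plan_topographic_path(open, a, a)
  expect_equal(block_path_time(p) * 60, 2 * 7.2)
})
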