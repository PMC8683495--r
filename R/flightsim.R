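#' Euclidean flight time
#'
#' Straight-line flight at cruise speed, the pathway model of earlier drone
#' AED studies: no climb over obstacles, no acceleration profile.
#'
#' @param distance_m ground distance in metres (>= 0).
#' @param cruise_speed_kmh cruise speed in km/h (default 50, the performance
#'   ceiling of the simulated airframe).
#' @return flight time in minutes, rounded to 2 decimals.
#' @export
euclidean_flight_time <- function(distance_m, cruise_speed_kmh = 50) {
  if (any(distance_m < 0)) stop("distance must be non-negative")
  if (cruise_speed_kmh <= 0) stop("cruise speed must be positive")
  round(distance_m / (cruise_speed_kmh * 1000 / 60), 2)
}

#' Maximum obstacle altitude along a flight corridor
#'
#' Scans the straight segment from `a` to `b` with a corridor of the given
#' half-width and returns the maximum of elevation plus building height over
#' the terrain cells the corridor touches (cell centre within
#' `halfwidth + cell_size/2` of the segment, so cells merely clipped by the
#' corridor edge count).
#'
#' @param grid a [terrain_grid()].
#' @param a,b numeric `c(x, y)` endpoints in metres; must lie inside the
#'   grid.
#' @param halfwidth corridor half-width in metres (default 5, one block).
#' @return the corridor's maximum obstacle top altitude (m).
#' @export
corridor_max_altitude <- function(grid, a, b, halfwidth = 5) {
  g <- raster_grid(grid$elevation, grid$origin, grid$cell_size)
  point_to_cell(g, c(a[1], b[1]), c(a[2], b[2]))   # errors if outside
  cc <- cell_centers(g)
  pad <- halfwidth + grid$cell_size / 2
  ix <- which(cc$x >= min(a[1], b[1]) - pad & cc$x <= max(a[1], b[1]) + pad)
  iy <- which(cc$y >= min(a[2], b[2]) - pad & cc$y <= max(a[2], b[2]) + pad)
  px <- rep(cc$x[ix], each = length(iy))
  py <- rep(cc$y[iy], times = length(ix))
  d <- point_segment_distance(px, py, a, b)
  sel <- d <= pad    # column-major over the [iy, ix] window, matching px/py
  tops <- (grid$elevation + grid$building_height)[iy, ix, drop = FALSE]
  max(tops[sel])
}

# Distance from points (px, py) to the segment a-b.
point_segment_distance <- function(px, py, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  L2 <- vx^2 + vy^2
  if (L2 == 0) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- pmin(pmax(((px - a[1]) * vx + (py - a[2]) * vy) / L2, 0), 1)
  sqrt((px - (a[1] + t * vx))^2 + (py - (a[2] + t * vy))^2)
}

#' Block traversal-time database
#'
#' Lookup table keyed by (entry speed bin, entry direction, escape speed
#' bin, escape direction) giving the measured seconds to cross one 10 m
#' airspace block. Keys not in the table fall back to the analytic default
#' (see [block_path_time()]). Speed bins are km/h in steps of 10, capped at
#' 50.
#'
#' The packaged default holds the one published bench measurement — a
#' 10 km/h downward entry followed by a 10 km/h rightward escape takes
#' 3.25 s — with every other combination served by the analytic fallback;
#' supply a fuller bench-measured table via [read_traversal_db()] when one
#' is available.
#'
#' @return data.frame with columns `entry_speed`, `entry_dir`,
#'   `escape_speed`, `escape_dir`, `seconds`.
#' @export
default_traversal_db <- function() {
  db <- data.frame(entry_speed = 10, entry_dir = "down",
                   escape_speed = 10, escape_dir = "right",
                   seconds = 3.25)
  validate_traversal_db(db)
}

#' @rdname default_traversal_db
#' @param path CSV file with the five documented columns.
#' @export
read_traversal_db <- function(path) {
  validate_traversal_db(utils::read.csv(path, stringsAsFactors = FALSE))
}

validate_traversal_db <- function(db) {
  need <- c("entry_speed", "entry_dir", "escape_speed", "escape_dir",
            "seconds")
  if (!all(need %in% names(db))) {
    stop("traversal DB needs columns: ", paste(need, collapse = ", "))
  }
  dirs <- c("up", "down", "forward", "left", "right")
  stopifnot(all(db$entry_dir %in% dirs), all(db$escape_dir %in% dirs),
            all(db$seconds > 0),
            all(db$entry_speed <= 50), all(db$escape_speed <= 50))
  class(db) <- c("traversal_db", "data.frame")
  db
}

# Seconds to traverse one block. DB lookup first; analytic fallback is the
# constant-acceleration estimate 2L / (v_in + v_out); a standing start and
# stop (both zero) is modelled as two half-blocks to/from the first speed
# bin: 7.2 s.
block_seconds <- function(entry_speed, entry_dir, escape_speed, escape_dir,
                          db, block_size = 10) {
  hit <- db$entry_speed == entry_speed & db$entry_dir == entry_dir &
    db$escape_speed == escape_speed & db$escape_dir == escape_dir
  if (any(hit)) return(db$seconds[which(hit)[1]])
  vsum <- (entry_speed + escape_speed) / 3.6   # km/h -> m/s
  if (vsum <= 0) {
    half <- 2 * (block_size / 2) / (10 / 3.6)
    return(2 * half)
  }
  2 * block_size / vsum
}

# Block-boundary speed profile for one segment: ramp from v_in toward the
# 50 km/h cap in 10 km/h steps per block, decelerating into v_out.
segment_speeds <- function(n, v_in, v_out, vmax = 50, step = 10) {
  j <- 0:n
  pmin(pmin(v_in + step * j, v_out + step * (n - j)), vmax)
}

#' Plan a topographic flight path
#'
#' The obstacle-aware pathway: climb vertically from the station to a cruise
#' altitude one clearance above the tallest obstacle in the corridor to the
#' scene, cruise horizontally the Euclidean ground distance, then descend
#' vertically to the scene. Each leg is decomposed into 10 m blocks
#' annotated with entry/escape speeds (ramping from standstill, one
#' 10 km/h bin per block, capped at the cruise speed) and directions, ready
#' for traversal-time lookup.
#'
#' @param grid a [terrain_grid()].
#' @param station,site numeric `c(x, y)` in metres, inside the grid.
#' @param clearance metres of clearance above the corridor's tallest
#'   obstacle (default 10, one block).
#' @param block_size block edge length in metres (default 10).
#' @return a `flight_plan`: station/site coordinates and ground altitudes,
#'   `cruise_altitude`, block counts `n_climb`, `n_cruise`, `n_descent`, and
#'   a `blocks` data.frame with per-block entry/escape annotations.
#' @export
plan_topographic_path <- function(grid, station, site, clearance = 10,
                                  block_size = 10) {
  station_alt <- ground_elevation(grid, station[1], station[2])
  site_alt <- ground_elevation(grid, site[1], site[2])
  ceiling_alt <- corridor_max_altitude(grid, station, site)
  cruise_alt <- max(ceiling_alt, station_alt, site_alt) + clearance
  dist <- sqrt(sum((site - station)^2))

  n_climb <- ceiling((cruise_alt - station_alt) / block_size)
  n_cruise <- ceiling(dist / block_size)
  n_descent <- ceiling((cruise_alt - site_alt) / block_size)

  corner1 <- if (n_cruise > 0) "forward" else "down"
  blocks <- rbind(
    segment_blocks(n_climb, "up", corner1, v_in = 0,
                   v_out = if (n_cruise + n_descent > 0) 10 else 0),
    segment_blocks(n_cruise, "forward", "down", v_in = 10,
                   v_out = if (n_descent > 0) 10 else 0),
    segment_blocks(n_descent, "down", "down", v_in = 10, v_out = 0))

  structure(list(station = station, site = site,
                 station_alt = station_alt, site_alt = site_alt,
                 cruise_altitude = cruise_alt, distance = dist,
                 n_climb = n_climb, n_cruise = n_cruise,
                 n_descent = n_descent, blocks = blocks),
            class = "flight_plan")
}

# Annotated blocks for one leg; the last block escapes in the next leg's
# direction (the corner of the flight path).
segment_blocks <- function(n, dir, next_dir, v_in, v_out) {
  if (n == 0) {
    return(data.frame(entry_speed = numeric(0), entry_dir = character(0),
                      escape_speed = numeric(0), escape_dir = character(0)))
  }
  vb <- segment_speeds(n, v_in, v_out)
  data.frame(entry_speed = vb[seq_len(n)], entry_dir = dir,
             escape_speed = vb[seq_len(n) + 1],
             escape_dir = c(rep(dir, n - 1), next_dir))
}

#' @export
print.flight_plan <- function(x, ...) {
  cat(sprintf(paste0("flight_plan: %.0f m ground distance, cruise at %.0f m",
                     " (%d climb + %d cruise + %d descent blocks)\n"),
              x$distance, x$cruise_altitude, x$n_climb, x$n_cruise,
              x$n_descent))
  invisible(x)
}

#' Flight time along a planned block path
#'
#' Sums the traversal time of every block in the plan, taking each block's
#' time from the measured database where a matching (entry speed, entry
#' direction, escape speed, escape direction) key exists and otherwise from
#' the analytic constant-acceleration fallback
#' `2 * 10 m / (v_entry + v_escape)` (speeds in m/s).
#'
#' @param plan a [plan_topographic_path()] result, or any object with a
#'   `blocks` data.frame.
#' @param db a traversal database (default [default_traversal_db()]).
#' @return flight time in minutes.
#' @export
block_path_time <- function(plan, db = default_traversal_db()) {
  blocks <- if (is.data.frame(plan)) plan else plan$blocks
  if (nrow(blocks) == 0) return(0)
  secs <- vapply(seq_len(nrow(blocks)), function(i) {
    block_seconds(blocks$entry_speed[i], blocks$entry_dir[i],
                  blocks$escape_speed[i], blocks$escape_dir[i], db)
  }, 0)
  sum(secs) / 60
}

#' Topographic flight time between two points
#'
#' Convenience wrapper: plan the climb-cruise-descend path and evaluate it
#' against a traversal database.
#'
#' @inheritParams plan_topographic_path
#' @inheritParams block_path_time
#' @return flight time in minutes.
#' @export
topographic_flight_time <- function(grid, station, site,
                                    db = default_traversal_db(),
                                    clearance = 10) {
  block_path_time(plan_topographic_path(grid, station, site,
                                        clearance = clearance), db)
}
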