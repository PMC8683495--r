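#' Build an analysis lattice over the city extent
#'
#' @param extent `c(width, height)` in metres.
#' @param cell_size lattice resolution in metres (default 50).
#' @param origin lower-left corner (m).
#' @return a zero-valued [raster_grid()] covering the extent.
#' @export
make_lattice <- function(extent, cell_size = 50, origin = c(0, 0)) {
  nx <- ceiling(extent[1] / cell_size)
  ny <- ceiling(extent[2] / cell_size)
  raster_grid(matrix(0, ny, nx), origin = origin, cell_size = cell_size)
}

# min-max rescale to [0, 1]; a flat layer (including all-zero) maps to 0.
minmax_normalize <- function(m) {
  rng <- range(m)
  if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
}

#' Kernel-density occurrence layer
#'
#' Evaluates, at every lattice cell centre, the sum of a quartic (biweight)
#' kernel `(1 - (d/r)^2)^2` over the event locations, truncated at the
#' kernel radius — the standard GIS heat-map. The layer is then min-max
#' normalized to `[0, 1]` so it can be combined 1:1 with the response-time
#' layer; an event-free (all-zero) layer stays zero.
#'
#' @param events data.frame with columns `x`, `y` (m); may be empty.
#' @param lattice a [raster_grid()] defining the evaluation lattice.
#' @param radius kernel radius in metres (default 300).
#' @param normalize min-max normalize the layer (default `TRUE`); set
#'   `FALSE` to obtain raw kernel sums.
#' @return a [raster_grid()] on the same lattice.
#' @export
heatmap_layer <- function(events, lattice, radius = 300, normalize = TRUE) {
  if (radius <= 0) stop("radius must be > 0")
  cc <- cell_centers(lattice)
  d <- dim(lattice$values)
  vals <- matrix(0, d[1], d[2])
  cs <- lattice$cell_size
  for (i in seq_len(nrow(events))) {
    ex <- events$x[i]; ey <- events$y[i]
    ix <- which(abs(cc$x - ex) <= radius)
    iy <- which(abs(cc$y - ey) <= radius)
    if (!length(ix) || !length(iy)) next
    d2 <- outer((cc$y[iy] - ey)^2, (cc$x[ix] - ex)^2, `+`)
    k <- (1 - d2 / radius^2)^2
    k[d2 > radius^2] <- 0
    vals[iy, ix] <- vals[iy, ix] + k
  }
  if (normalize) vals <- minmax_normalize(vals)
  raster_grid(vals, lattice$origin, cs)
}

#' Inverse-distance-weighted response-time layer
#'
#' Interpolates sampled EMS response times onto the lattice with inverse
#' distance weighting: `sum(w_i t_i) / sum(w_i)`, `w_i = d_i^(-power)`, using
#' all sample points. A cell whose centre coincides with a sample point
#' (distance below `cell_size / 100`) takes that sample's value exactly.
#'
#' @param samples data.frame with columns `x`, `y` (m) and `value`
#'   (response time, min); at least one row.
#' @param lattice a [raster_grid()].
#' @param power the distance-decay exponent (default 2).
#' @param normalize min-max normalize the layer (default `TRUE`).
#' @return a [raster_grid()] on the same lattice.
#' @export
idw_layer <- function(samples, lattice, power = 2, normalize = TRUE) {
  if (nrow(samples) == 0) stop("IDW interpolation needs at least one sample point")
  if (power <= 0) stop("power must be > 0")
  cc <- cell_centers(lattice)
  d <- dim(lattice$values)
  gx <- rep(cc$x, each = d[1])
  gy <- rep(cc$y, times = d[2])
  eps <- lattice$cell_size / 100
  num <- numeric(length(gx))
  den <- numeric(length(gx))
  exact <- rep(NA_real_, length(gx))
  exact_d <- rep(Inf, length(gx))
  for (i in seq_len(nrow(samples))) {
    di <- sqrt((gx - samples$x[i])^2 + (gy - samples$y[i])^2)
    hit <- di < eps & di < exact_d
    exact[hit] <- samples$value[i]
    exact_d[hit] <- di[hit]
    w <- pmax(di, eps / 2)^(-power)
    num <- num + w * samples$value[i]
    den <- den + w
  }
  v <- num / den
  v[!is.na(exact)] <- exact[!is.na(exact)]
  vals <- matrix(v, d[1], d[2])
  if (normalize) vals <- minmax_normalize(vals)
  raster_grid(vals, lattice$origin, lattice$cell_size)
}

#' Combine occurrence and response-time layers into the OHCA risk map
#'
#' Weighted sum of the two `[0, 1]`-normalized layers on the shared 50 m
#' lattice (default 1:1 weighting).
#'
#' @param heat,response [raster_grid()] layers on the same lattice.
#' @param weights numeric length-2 `c(w_heat, w_response)`.
#' @return a `risk_map` (a [raster_grid()] subclass).
#' @export
combine_risk <- function(heat, response, weights = c(1, 1)) {
  if (!identical(dim(heat$values), dim(response$values)) ||
      !isTRUE(all.equal(heat$origin, response$origin)) ||
      !isTRUE(all.equal(heat$cell_size, response$cell_size))) {
    stop("risk layers must share the same lattice")
  }
  score <- weights[1] * heat$values + weights[2] * response$values
  if (any(!is.finite(score)) || any(score < 0)) {
    stop("risk scores must be finite and non-negative")
  }
  out <- raster_grid(score, heat$origin, heat$cell_size)
  class(out) <- c("risk_map", class(out))
  out
}
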