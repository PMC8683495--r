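#' Planar raster grid
#'
#' A minimal raster container used throughout the package: a numeric matrix
#' of cell values on a regular planar lattice in metres. Row `iy`, column
#' `ix` covers the half-open square
#' `[x0 + (ix-1)*cs, x0 + ix*cs) x [y0 + (iy-1)*cs, y0 + iy*cs)`,
#' with its centre at `(x0 + (ix-0.5)*cs, y0 + (iy-0.5)*cs)`.
#'
#' @param values numeric matrix, rows indexing y and columns indexing x.
#' @param origin numeric length-2, planar coordinates (m) of the lower-left
#'   corner.
#' @param cell_size cell edge length in metres.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin = c(0, 0), cell_size = 10) {
  stopifnot(is.matrix(values), is.numeric(values),
            length(origin) == 2, is.finite(origin),
            length(cell_size) == 1, cell_size > 0)
  structure(list(values = values, origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size)),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("raster_grid: %d x %d cells of %g m, origin (%g, %g)\n",
              d[1], d[2], x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  values: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Cell-centre coordinates of a raster grid
#'
#' @param grid a [raster_grid()].
#' @return list with numeric vectors `x` (length ncol) and `y` (length nrow).
#' @export
cell_centers <- function(grid) {
  d <- dim(grid$values)
  list(x = grid$origin[1] + (seq_len(d[2]) - 0.5) * grid$cell_size,
       y = grid$origin[2] + (seq_len(d[1]) - 0.5) * grid$cell_size)
}

#' Locate the cell containing a point
#'
#' Membership is half-open: a point on the shared edge of two cells belongs
#' to the cell on its upper/right side's lower edge, i.e. `[x, x + cs)`.
#'
#' @param grid a [raster_grid()].
#' @param x,y planar coordinates (m); vectors recycle.
#' @return data.frame with integer columns `ix`, `iy` (1-based); an error if
#'   any point falls outside the grid.
#' @export
point_to_cell <- function(grid, x, y) {
  d <- dim(grid$values)
  ix <- floor((x - grid$origin[1]) / grid$cell_size) + 1L
  iy <- floor((y - grid$origin[2]) / grid$cell_size) + 1L
  if (any(ix < 1L | ix > d[2] | iy < 1L | iy > d[1])) {
    stop("point outside grid extent")
  }
  data.frame(ix = as.integer(ix), iy = as.integer(iy))
}

#' Read and write rasters as ESRI ASCII grid
#'
#' Plain-text raster interchange format (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values from north to south.
#'
#' @param grid a [raster_grid()].
#' @param path file path.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a [raster_grid()].
#' @export
write_ascii_grid <- function(grid, path) {
  d <- dim(grid$values)
  hdr <- c(sprintf("ncols %d", d[2]),
           sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.6f", grid$origin[1]),
           sprintf("yllcorner %.6f", grid$origin[2]),
           sprintf("cellsize %.6f", grid$cell_size),
           "NODATA_value -9999")
  rows <- apply(grid$values[rev(seq_len(d[1])), , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                  collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, function(h) as.numeric(h[2]), 0),
                        tolower(vapply(hdr, `[`, "", 1)))
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  vals[vals == kv[["nodata_value"]]] <- NA_real_
  raster_grid(vals[rev(seq_len(nrow(vals))), , drop = FALSE],
              origin = c(kv[["xllcorner"]], kv[["yllcorner"]]),
              cell_size = kv[["cellsize"]])
}
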