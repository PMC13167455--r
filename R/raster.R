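#' Grid geometry for landscape rasters
#'
#' All rasters and utilization distributions in this package share a simple
#' regular-grid convention: square cells of side `cellsize` metres, origin at
#' the lower-left *corner* of the grid, and values attached to cell centres.
#' The centre of cell `(ix, iy)` is at
#' `origin + (ix - 0.5, iy - 0.5) * cellsize`. Coordinates are in metres in a
#' local projected frame (no CRS is attached).
#'
#' @param origin numeric length-2, lower-left corner (x0, y0) in metres.
#' @param cellsize cell side length in metres (> 0).
#' @param nx,ny number of cells along x and y.
#' @return an object of class `grid_geom`.
#' @export
grid_geom <- function(origin = c(0, 0), cellsize = 30, nx = 200, ny = 200) {
  stopifnot(length(origin) == 2, is.finite(origin))
  if (!is.finite(cellsize) || cellsize <= 0) stop("cellsize must be > 0")
  if (nx < 1 || ny < 1) stop("grid must have at least one cell")
  structure(list(origin = as.numeric(origin), cellsize = as.numeric(cellsize),
                 nx = as.integer(nx), ny = as.integer(ny)),
            class = "grid_geom")
}

#' @export
print.grid_geom <- function(x, ...) {
  cat(sprintf("<grid_geom> %d x %d cells, %g m, origin (%g, %g)\n",
              x$nx, x$ny, x$cellsize, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param geom a [grid_geom()].
#' @return list with vectors `x` (length nx) and `y` (length ny) of cell-centre
#'   coordinates.
#' @export
cell_centres <- function(geom) {
  list(x = geom$origin[1] + (seq_len(geom$nx) - 0.5) * geom$cellsize,
       y = geom$origin[2] + (seq_len(geom$ny) - 0.5) * geom$cellsize)
}

#' Area of one grid cell in square metres
#' @param geom a [grid_geom()].
#' @export
cell_area <- function(geom) geom$cellsize^2

same_geom <- function(a, b, tol = 1e-9) {
  a$nx == b$nx && a$ny == b$ny &&
    abs(a$cellsize - b$cellsize) <= tol &&
    all(abs(a$origin - b$origin) <= tol)
}

#' A raster on a shared grid
#'
#' Thin container pairing a value matrix with its [grid_geom()]. The matrix is
#' indexed `values[ix, iy]` with `ix` running west to east and `iy` south to
#' north. `NA` encodes missing (masked) cells.
#'
#' @param values numeric matrix of dimension `c(nx, ny)`.
#' @param geom a [grid_geom()].
#' @export
grid_raster <- function(values, geom) {
  values <- as.matrix(values)
  if (!identical(dim(values), c(geom$nx, geom$ny)))
    stop(sprintf("values must be an %d x %d matrix", geom$nx, geom$ny))
  structure(list(values = values, geom = geom), class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_raster> %d x %d, range [%g, %g], %d NA\n",
              x$geom$nx, x$geom$ny,
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' Convert a grid raster to a long data frame
#' @param x a [grid_raster()].
#' @param ... unused.
#' @export
as.data.frame.grid_raster <- function(x, ...) {
  cc <- cell_centres(x$geom)
  data.frame(x = rep(cc$x, times = x$geom$ny),
             y = rep(cc$y, each = x$geom$nx),
             value = as.vector(x$values))
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format (`.asc`) preserving the grid geometry
#' (ncols/nrows/xllcorner/yllcorner/cellsize) so rasters round-trip through
#' standard GIS tools. Missing cells are written as the nodata value.
#'
#' @param r a [grid_raster()].
#' @param path file path.
#' @param nodata nodata sentinel written for `NA` cells.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  g <- r$geom
  hdr <- c(sprintf("ncols %d", g$nx), sprintf("nrows %d", g$ny),
           sprintf("xllcorner %.10g", g$origin[1]),
           sprintf("yllcorner %.10g", g$origin[2]),
           sprintf("cellsize %.10g", g$cellsize),
           sprintf("NODATA_value %g", nodata))
  v <- r$values
  v[is.na(v)] <- nodata
  # ASCII grids are written north to south: row 1 = top row of the map
  rows <- vapply(rev(seq_len(g$ny)), function(iy)
    paste(format(v[, iy], trim = TRUE, digits = 10), collapse = " "), "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  ln <- readLines(path)
  hv <- function(key) {
    i <- grep(paste0("^", key, " "), ln, ignore.case = TRUE)[1]
    as.numeric(strsplit(trimws(ln[i]), "\\s+")[[1]][2])
  }
  nx <- as.integer(hv("ncols")); ny <- as.integer(hv("nrows"))
  geom <- grid_geom(c(hv("xllcorner"), hv("yllcorner")), hv("cellsize"), nx, ny)
  nodata <- hv("NODATA_value")
  dat <- scan(text = paste(ln[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(dat, nrow = ny, ncol = nx, byrow = TRUE)  # north-to-south rows
  v <- t(m[rev(seq_len(ny)), , drop = FALSE])
  v[v == nodata] <- NA_real_
  grid_raster(v, geom)
}
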