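#' Export a home range as GeoJSON
#'
#' Writes the range's cell set as a MultiPolygon of column-wise merged cell
#' rectangles (exact cell-mass geometry, no smoothing), with level, area, SE
#' and centroid in the feature properties. Coordinates are the local metric
#' frame of the grid.
#'
#' @param hr a [hr_contour()] home range.
#' @param path output file path.
#' @export
write_hr_geojson <- function(hr, path) {
  g <- hr$geom
  cs <- g$cellsize
  ix <- ((hr$cells - 1) %% g$nx) + 1
  iy <- ((hr$cells - 1) %/% g$nx) + 1
  polys <- list()
  for (col in sort(unique(ix))) {
    ys <- sort(iy[ix == col])
    runs <- split(ys, cumsum(c(1, diff(ys) != 1)))
    x0 <- g$origin[1] + (col - 1) * cs
    for (r in runs) {
      y0 <- g$origin[2] + (min(r) - 1) * cs
      y1 <- g$origin[2] + max(r) * cs
      ring <- list(c(x0, y0), c(x0 + cs, y0), c(x0 + cs, y1), c(x0, y1),
                   c(x0, y0))
      polys[[length(polys) + 1L]] <- list(ring)
    }
  }
  feature <- list(
    type = "Feature",
    geometry = list(type = "MultiPolygon", coordinates = polys),
    properties = list(level = hr$level, area_m2 = hr$area, se_m2 = hr$se,
                      centroid_x = unname(hr$centroid["x"]),
                      centroid_y = unname(hr$centroid["y"]),
                      group_id = hr$group_id, period = hr$period,
                      note = "local metric coordinates, cell-centre grid"))
  fc <- list(type = "FeatureCollection", features = list(feature))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
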