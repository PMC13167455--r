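#' Normalized difference vegetation index from RED/NIR reflectance
#'
#' NDVI = (NIR - RED) / (NIR + RED), computed per cell. Cells flagged by the
#' quality-assessment mask (cloud/shadow contamination) or with zero total
#' reflectance become missing; missingness then propagates through all
#' downstream arithmetic.
#'
#' @param red,nir [grid_raster()]s of surface reflectance in `[0, 1]`.
#' @param qa optional logical [grid_raster()]; `TRUE` marks contaminated cells.
#' @return a [grid_raster()] of NDVI values in `[-1, 1]` (NA where masked).
#' @export
compute_ndvi <- function(red, nir, qa = NULL) {
  if (!same_geom(red$geom, nir$geom)) stop("red and nir grids do not match")
  if (any(red$values < 0, na.rm = TRUE) || any(nir$values < 0, na.rm = TRUE))
    stop("reflectances must be >= 0")
  s <- nir$values + red$values
  v <- (nir$values - red$values) / s
  v[!is.na(s) & s == 0] <- NA_real_
  if (!is.null(qa)) {
    if (!same_geom(red$geom, qa$geom)) stop("qa grid does not match")
    v[qa$values != 0] <- NA_real_
  }
  grid_raster(v, red$geom)
}

#' Pixel-wise maximum composite of NDVI rasters
#'
#' Per-cell maximum across rasters, skipping missing values; a cell missing in
#' every input stays missing. Maximum compositing suppresses residual cloud
#' contamination, which biases NDVI downward.
#'
#' @param rasters non-empty list of [grid_raster()]s on one grid.
#' @return a [grid_raster()].
#' @export
max_composite <- function(rasters) {
  if (length(rasters) == 0) stop("empty raster list")
  g <- rasters[[1]]$geom
  for (r in rasters) if (!same_geom(r$geom, g)) stop("raster grids do not match")
  arr <- vapply(rasters, function(r) r$values, rasters[[1]]$values)
  dim(arr) <- c(g$nx * g$ny, length(rasters))
  v <- apply(arr, 1, function(z) if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE))
  grid_raster(matrix(v, g$nx, g$ny), g)
}

#' Seasonal maximum-NDVI composite from an image stack
#'
#' Computes NDVI for every image of a [gen_landscape()] stack whose timestamp
#' falls in the requested seasonal window (months 2-4 for the peak dry season,
#' 9-11 for the peak wet season) and returns their pixel-wise maximum
#' composite.
#'
#' @param stack a `landscape_stack` from [gen_landscape()].
#' @param year study year.
#' @param season `"dry"` or `"wet"`.
#' @return a [grid_raster()] of composite NDVI.
#' @export
seasonal_composite <- function(stack, year, season = c("dry", "wet")) {
  season <- match.arg(season)
  months <- if (season == "dry") 2:4 else 9:11
  sel <- Filter(function(im) im$year == year && im$month %in% months,
                stack$images)
  if (length(sel) == 0)
    stop(sprintf("no images in the %s-season window of %s", season, year))
  max_composite(lapply(sel, function(im) {
    r <- realize_image(stack, im)
    compute_ndvi(r$red, r$nir, r$qa)
  }))
}

#' Standardize a climate-anomaly series within seasons
#'
#' Z-scores the raw anomaly separately within each season label (sample sd,
#' n - 1 denominator), so that values measure departure from conditions
#' typical *for that season* and season and anomaly enter models without
#' collinearity.
#'
#' @param series data.frame with columns `season` and `spei_raw`.
#' @return the series with a `spei_z` column (replaced if present).
#' @export
standardize_spei <- function(series) {
  stopifnot(all(c("season", "spei_raw") %in% names(series)))
  z <- stats::ave(series$spei_raw, series$season, FUN = function(v) {
    if (length(unique(v)) < 2) stop("need >= 2 distinct values per season")
    s <- stats::sd(v)
    if (s == 0) stop("zero variance within a season")
    (v - mean(v)) / s
  })
  series$spei_z <- z
  series
}

#' Mean raster value within a home range
#'
#' Zonal mean over the unmasked cells whose centres fall inside the range
#' (cell-centre rule, no partial-cell weighting). Home ranges in this package
#' are stored as grid cell sets, so membership is exact.
#'
#' @param raster a [grid_raster()].
#' @param hr a [hr_contour()] home range on the same grid.
#' @return list with `mean` and `n_cells` (unmasked cells used).
#' @export
mean_raster_in_range <- function(raster, hr) {
  if (!same_geom(raster$geom, hr$geom)) stop("raster and range grids do not match")
  vals <- raster$values[hr$cells]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no unmasked cells inside the range")
  list(mean = mean(vals), n_cells = length(vals))
}
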