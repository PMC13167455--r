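#' Generate a synthetic riparian landscape with seasonal RED/NIR imagery
#'
#' Builds a shared landscape grid (default 200 x 200 cells at 30 m, matching
#' Landsat resolution) crossed by a sinuous river, and a stack of seasonal
#' reflectance images. True greenness follows the dry-forest pattern the
#' package targets: in the dry season NDVI decays steeply with distance from
#' the river (resources concentrate in evergreen riparian zones), while in the
#' wet season the landscape greens up and is spatially much flatter. Each
#' image adds sensor noise, a downward "haze" bias (so maximum composites are
#' the right summary) and a random cloud QA mask.
#'
#' Images are stored as light-weight descriptors and realized on demand by
#' [realize_image()], deterministically from (config, seed).
#'
#' @param config list of overrides: `nx`, `ny`, `cellsize`, `origin`.
#' @param years years to cover.
#' @param climate optional [gen_climate()] table; when supplied, year-season
#'   greenness levels shift with the standardized anomaly (wet anomalies
#'   green up the landscape).
#' @param truth a [default_truth()] configuration (`landscape` section).
#' @param seed integer master seed.
#' @return an object of class `landscape_stack`: `geom`,
#'   `riparian_distance` ([grid_raster()], metres), `river` (polyline matrix),
#'   `images` (descriptor list), `truth`, `seed`.
#' @export
gen_landscape <- function(config = list(), years = integer(0), climate = NULL,
                          truth = default_truth(), seed = 1) {
  cfg <- utils::modifyList(
    list(nx = 200, ny = 200, cellsize = 30, origin = c(0, 0)), config)
  if (cfg$cellsize <= 0) stop("cell size must be > 0")
  if (cfg$nx < 50 || cfg$ny < 50) stop("grid must be at least 50 x 50 cells")
  geom <- grid_geom(cfg$origin, cfg$cellsize, cfg$nx, cfg$ny)
  lcf <- truth$landscape
  with_seed(substream_seed(seed, "landscape"), {
    ext <- c(geom$nx, geom$ny) * geom$cellsize
    # sinuous river running west-east through the middle of the map
    xs <- seq(geom$origin[1], geom$origin[1] + ext[1], by = geom$cellsize / 2)
    amp <- 0.15 * ext[2]
    ys <- geom$origin[2] + 0.5 * ext[2] +
      amp * sin(2 * pi * 1.3 * (xs - geom$origin[1]) / ext[1]) +
      0.4 * amp * sin(2 * pi * 3.1 * (xs - geom$origin[1]) / ext[1] + 1)
    river <- cbind(x = xs, y = ys)
    rip <- distance_to_polyline(geom, river)
    img <- list()
    for (yr in years) for (season in c("dry", "wet")) {
      lev <- 0
      if (!is.null(climate)) {
        i <- which(climate$year == yr & climate$season == season)
        if (length(i) == 1) lev <- 0.03 * climate$spei_z[i]
      }
      lev <- lev + stats::rnorm(1, 0, 0.01)
      months <- if (season == "dry") 2:4 else 9:11
      for (k in seq_len(lcf$n_images)) {
        img[[length(img) + 1L]] <- list(
          year = yr, season = season, month = months[1 + (k - 1) %% 3],
          index = k, level = lev,
          seed = substream_seed(seed, sprintf("image-%d-%s-%d", yr, season, k)))
      }
    }
    structure(list(geom = geom, riparian_distance = rip, river = river,
                   images = img, truth = lcf, seed = seed),
              class = "landscape_stack")
  })
}

distance_to_polyline <- function(geom, line) {
  cc <- cell_centres(geom)
  px <- rep(cc$x, times = geom$ny)
  py <- rep(cc$y, each = geom$nx)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(line)))
    d2 <- pmin(d2, (px - line[i, 1])^2 + (py - line[i, 2])^2)
  grid_raster(matrix(sqrt(d2), geom$nx, geom$ny), geom)
}

#' True (noise-free) NDVI surface of a synthetic landscape
#'
#' @param stack a [gen_landscape()] object.
#' @param season `"dry"` or `"wet"`.
#' @param level additive year-season greenness shift (NDVI units).
#' @return a [grid_raster()] of NDVI.
#' @export
true_ndvi <- function(stack, season = c("dry", "wet"), level = 0) {
  season <- match.arg(season)
  lcf <- stack$truth
  d <- stack$riparian_distance$values
  v <- if (season == "dry")
    lcf$ndvi_bg_dry + lcf$ndvi_rip_dry * exp(-d / lcf$decay_dry)
  else
    lcf$ndvi_bg_wet + lcf$ndvi_rip_wet * exp(-d / lcf$decay_wet)
  grid_raster(pmin(pmax(v + level, -0.99), 0.99), stack$geom)
}

#' Realize one RED/NIR/QA image from its descriptor
#'
#' Reconstructs the reflectance bands deterministically from the descriptor's
#' substream seed. NDVI is mapped to reflectance with a fixed band sum `s`
#' (`NIR = s (1 + NDVI) / 2`, `RED = s (1 - NDVI) / 2`), both clipped to
#' `[0, 1]`.
#'
#' @param stack a [gen_landscape()] object.
#' @param image one element of `stack$images`.
#' @return list with [grid_raster()]s `red`, `nir`, `qa` and the descriptor
#'   fields.
#' @export
realize_image <- function(stack, image) {
  geom <- stack$geom
  lcf <- stack$truth
  with_seed(image$seed, {
    n <- geom$nx * geom$ny
    ndvi <- true_ndvi(stack, image$season, image$level)$values +
      stats::rnorm(n, 0, lcf$image_noise_sd) -
      abs(stats::rnorm(1, 0, lcf$haze_sd))     # haze only ever dims greenness
    ndvi <- pmin(pmax(ndvi, -0.99), 0.99)
    s <- lcf$reflectance_sum
    nir <- grid_raster(matrix(s * (1 + ndvi) / 2, geom$nx, geom$ny), geom)
    red <- grid_raster(matrix(s * (1 - ndvi) / 2, geom$nx, geom$ny), geom)
    qa <- grid_raster(matrix(stats::runif(n) < lcf$qa_fraction, geom$nx, geom$ny),
                      geom)
    c(list(red = red, nir = nir, qa = qa), image)
  })
}
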