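#' Directed proportional overlap between two home ranges
#'
#' `PO_fn = IA_fn / HRA_f`: the fraction of the focal group's range area
#' intersected by the neighbour's range. The intersection area `IA_fn` is
#' symmetric in the two groups; dividing by the focal area makes the measure
#' directional -- it reads as the degree of neighbour encroachment onto the
#' focal range. Computed exactly on the shared grid as cell-set intersection.
#'
#' @param hr_f,hr_n [hr_contour()] home ranges on the same grid.
#' @return list: `po` in `[0, 1]`, `ia` (m^2), `hra_focal` (m^2).
#' @export
proportional_overlap <- function(hr_f, hr_n) {
  if (!same_geom(hr_f$geom, hr_n$geom)) stop("ranges are on different grids")
  if (length(hr_f$cells) == 0 || hr_f$area <= 0)
    stop("degenerate focal range (zero area)")
  ia <- length(intersect(hr_f$cells, hr_n$cells)) * cell_area(hr_f$geom)
  po <- ia / hr_f$area
  if (po > 1 && po <= 1 + 1e-9) po <- 1
  list(po = po, ia = ia, hra_focal = hr_f$area)
}

#' Overlap zone between two ranges, with area and mean greenness
#'
#' @param hr_f,hr_n [hr_contour()] home ranges on the same grid.
#' @param ndvi optional NDVI [grid_raster()] for the zonal mean.
#' @return list: `cells`, `area` (m^2, 0 if disjoint), `centroid` (NA if
#'   disjoint), `mean_ndvi` (NA if disjoint or no `ndvi`).
#' @export
overlap_zone <- function(hr_f, hr_n, ndvi = NULL) {
  if (!same_geom(hr_f$geom, hr_n$geom)) stop("ranges are on different grids")
  cells <- intersect(hr_f$cells, hr_n$cells)
  if (length(cells) == 0)
    return(list(cells = integer(0), area = 0,
                centroid = c(x = NA_real_, y = NA_real_),
                mean_ndvi = NA_real_))
  geom <- hr_f$geom
  cc <- cell_centres(geom)
  ix <- ((cells - 1) %% geom$nx) + 1
  iy <- ((cells - 1) %/% geom$nx) + 1
  zone <- list(cells = cells, area = length(cells) * cell_area(geom),
               centroid = c(x = mean(cc$x[ix]), y = mean(cc$y[iy])),
               mean_ndvi = NA_real_)
  if (!is.null(ndvi)) {
    hrz <- structure(list(cells = cells, geom = geom), class = "home_range")
    zone$mean_ndvi <- tryCatch(mean_raster_in_range(ndvi, hrz)$mean,
                               error = function(e) NA_real_)
  }
  zone
}

#' Encounter rate between two utilization distributions
#'
#' The relative probability that the two groups occupy the same unit area at
#' the same moment under independent stationary space use:
#' `ER = area_scale * integral(p_i(x) p_j(x) dx)`, evaluated on the shared
#' grid as `sum(p_i * p_j) * cell_area`. The measure is exactly symmetric in
#' its arguments. `area_scale` defaults to 1 m^2 and rescales the rate to any
#' encounter radius. An optional bootstrap resamples both UDs' points and
#' refits to give a standard error.
#'
#' @param ud_i,ud_j [ud_grid()]s on the same grid.
#' @param area_scale reference encounter area (m^2).
#' @param boot bootstrap replicates for the SE (0 = none; needs retained
#'   points in both UDs).
#' @return list: `er`, `se`, `log_se` (sd of log bootstrap rates).
#' @export
encounter_rate <- function(ud_i, ud_j, area_scale = 1, boot = 0) {
  if (!same_geom(ud_i$geom, ud_j$geom)) stop("UDs are on different grids")
  ca <- cell_area(ud_i$geom)
  er <- area_scale * sum(ud_i$values * ud_j$values) * ca
  out <- list(er = er, se = NA_real_, log_se = NA_real_)
  if (boot > 0) {
    if (is.null(ud_i$points) || is.null(ud_j$points))
      stop("bootstrap SE needs UDs with retained points")
    bs <- vapply(seq_len(boot), function(b) {
      u1 <- fit_ud(ud_i$points[sample.int(nrow(ud_i$points), replace = TRUE), ,
                               drop = FALSE], ud_i$geom, keep_points = FALSE)
      u2 <- fit_ud(ud_j$points[sample.int(nrow(ud_j$points), replace = TRUE), ,
                               drop = FALSE], ud_j$geom, keep_points = FALSE)
      area_scale * sum(u1$values * u2$values) * ca
    }, 0)
    out$se <- stats::sd(bs)
    out$log_se <- stats::sd(log(pmax(bs, 1e-300)))
  }
  out
}

#' Closed-form encounter rate for two Gaussian utilization distributions
#'
#' Reference value for [encounter_rate()]: for bivariate normal UDs the
#' product integral is the normal density of the centre separation,
#' `N(mu_i - mu_j; 0, Sigma_i + Sigma_j)`. Used as the analytic oracle for
#' grid-based encounter rates (mixtures combine bilinearly).
#'
#' @param mu_i,mu_j centres (length-2).
#' @param sigma_i,sigma_j isotropic standard deviations (m).
#' @param area_scale reference area (m^2).
#' @export
encounter_rate_gaussian <- function(mu_i, mu_j, sigma_i, sigma_j,
                                    area_scale = 1) {
  s2 <- sigma_i^2 + sigma_j^2
  d2 <- sum((mu_i - mu_j)^2)
  area_scale * exp(-d2 / (2 * s2)) / (2 * pi * s2)
}

#' Change in distance from a group's centroid to the overlap centroid
#'
#' `delta_d = D_{t+i} - D_t`, where `D` is the Euclidean distance from the
#' group's home-range centroid at time `t` to the overlap-zone centroid at
#' the two times. The sign is taken literally from this difference: negative
#' values mean the overlap centroid ended up closer to the group (consistent
#' with the group having shifted toward the shared zone), positive values
#' that it moved away.
#'
#' @param hr_g_t the group's [hr_contour()] range at time t.
#' @param overlap_t,overlap_ti [overlap_zone()]s at times t and t+i.
#' @return signed distance change in metres.
#' @export
delta_d <- function(hr_g_t, overlap_t, overlap_ti) {
  if (length(overlap_t$cells) == 0 || length(overlap_ti$cells) == 0)
    stop("delta_d needs non-empty overlap zones at both times")
  d0 <- sqrt(sum((hr_g_t$centroid - overlap_t$centroid)^2))
  d1 <- sqrt(sum((hr_g_t$centroid - overlap_ti$centroid)^2))
  d1 - d0
}

#' Assemble the double-entered directed dyad table for a set of ranges
#'
#' Computes [proportional_overlap()] in both directions for every pair of
#' home ranges sharing a period, attaching sizes from demography. Each
#' unordered pair-period yields exactly two rows with swapped roles and
#' identical intersection area.
#'
#' @param ranges named list of [hr_contour()]s for one period (names = group
#'   ids).
#' @param period period label.
#' @param sizes named integer vector of group sizes for the period.
#' @param season season label attached to the rows.
#' @return data.frame of directed records.
#' @export
directed_dyad_table <- function(ranges, period, sizes, season = "annual") {
  ids <- names(ranges)
  if (length(ids) < 2) stop("need at least two ranges")
  pairs <- t(utils::combn(ids, 2))
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    ab <- proportional_overlap(ranges[[a]], ranges[[b]])
    ba <- proportional_overlap(ranges[[b]], ranges[[a]])
    rows[[length(rows) + 1L]] <- data.frame(
      focal_id = c(a, b), neighbour_id = c(b, a),
      dyad_id = paste(a, b, sep = ":"), period = period, season = season,
      po = c(ab$po, ba$po), ia = c(ab$ia, ba$ia),
      hra_focal = c(ab$hra_focal, ba$hra_focal),
      focal_size = c(sizes[a], sizes[b]), neighbour_size = c(sizes[b], sizes[a]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
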