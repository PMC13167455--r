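#' Generate group-season space use: true UDs, trajectories and sleep sites
#'
#' Each group-season receives a bivariate (isotropic) Gaussian utilization
#' distribution whose true 95% area follows
#' `log(area) = a + b_size_hra * size_z + b_wet_hra * wet + noise`,
#' so larger groups hold larger ranges by construction. Range centres sit off
#' a per-group anchor on the river: in the wet season at the baseline
#' riparian distance, in the dry season pulled toward the river with strength
#' `placement_pull * size_z * (1 + placement_spei_mod * spei_z)` on the
#' log-distance scale -- larger groups claim the greener riparian cells, most
#' strongly in abnormally wet dry seasons and not at all at `spei_z = -1.5`.
#'
#' Movement is a stationary Ornstein-Uhlenbeck process around the UD centre
#' (position autocorrelation `exp(-dt/tau)`), sampled at a fixed interval over
#' a fixed number of tracking days; one sleep site per day is drawn from the
#' UD core. Group-seasons with a missing size are skipped with a warning.
#'
#' @param demography [gen_demography()] table.
#' @param landscape [gen_landscape()] object (supplies river geometry).
#' @param climate [gen_climate()] table covering the same years.
#' @param truth [default_truth()] configuration (`space_use` section).
#' @param seed integer master seed.
#' @param n_days tracking days simulated per group-season.
#' @param interval_min sampling interval in minutes.
#' @param day_hours tracked hours per day.
#' @return list of class `space_use`: `ud_params` (one row per group-season:
#'   centre, sigma, true area, sizes, anomaly), `trajectories` (long table of
#'   timestamped points) and `sleep_sites`.
#' @export
gen_space_use <- function(demography, landscape, climate,
                          truth = default_truth(), seed = 1,
                          n_days = 6, interval_min = 5, day_hours = 11.5) {
  cfg <- truth$space_use
  dem_years <- sort(unique(demography$year))
  if (!all(dem_years %in% climate$year))
    stop("demography and climate must cover identical periods")
  groups <- sort(unique(demography$group_id))
  anchors <- group_anchors(landscape, length(groups))
  rownames(anchors) <- groups
  with_seed(substream_seed(seed, "space-use"), {
    keys <- demography[order(demography$group_id, demography$year,
                             demography$season), ]
    ud <- list(); traj <- list(); sleeps <- list()
    for (i in seq_len(nrow(keys))) {
      row <- keys[i, ]
      if (is.na(row$size)) {
        warning(sprintf("skipping %s %d %s: size missing",
                        row$group_id, row$year, row$season))
        next
      }
      spei <- climate$spei_z[climate$year == row$year &
                               climate$season == row$season]
      wet <- as.numeric(row$season == "wet")
      log_area <- cfg$log_area_dry + cfg$b_size_hra * row$size_z +
        cfg$b_wet_hra * wet + stats::rnorm(1, 0, cfg$area_noise_sd)
      area <- exp(log_area)
      sigma <- sqrt(area / (pi * stats::qchisq(0.95, 2)))
      anc <- anchors[row$group_id, ]
      d <- if (wet == 1) cfg$riparian_d0 else
        cfg$riparian_dry *
          exp(-cfg$placement_pull * row$size_z *
                (1 + cfg$placement_spei_mod * spei))
      ctr <- c(anc["rx"] + d * anc["nx"], anc["ry"] + d * anc["ny"]) +
        stats::rnorm(2, 0, cfg$centre_jitter_sd)
      ud[[length(ud) + 1L]] <- data.frame(
        group_id = row$group_id, year = row$year, season = row$season,
        size = row$size, size_z = row$size_z, spei_z = spei,
        mu_x = ctr[1], mu_y = ctr[2], sigma = sigma,
        area95_true = area, tau_min = cfg$tau_min)
      n_per_day <- floor(day_hours * 60 / interval_min) + 1L
      rho <- exp(-interval_min / cfg$tau_min)
      for (dday in seq_len(n_days)) {
        pts <- ou_track(n_per_day, rho, sigma, ctr)
        date <- sprintf("%d-%02d-%02d", row$year,
                        if (row$season == "dry") 2L else 9L, dday)
        traj[[length(traj) + 1L]] <- data.frame(
          group_id = row$group_id, year = row$year, season = row$season,
          date = date, t = (seq_len(n_per_day) - 1) * interval_min * 60,
          x = pts[, 1], y = pts[, 2])
        sl <- ctr + stats::rnorm(2, 0, 0.5 * sigma)
        sleeps[[length(sleeps) + 1L]] <- data.frame(
          group_id = row$group_id, year = row$year, season = row$season,
          date = date, x = sl[1], y = sl[2])
      }
    }
    structure(list(ud_params = do.call(rbind, ud),
                   trajectories = do.call(rbind, traj),
                   sleep_sites = do.call(rbind, sleeps)),
              class = "space_use")
  })
}

# Evenly spaced stations along the river; each group's centre sits at
# distance d from its station along the (alternating-side) river normal.
group_anchors <- function(landscape, n_groups) {
  rv <- landscape$river
  idx <- round(seq(1, nrow(rv), length.out = n_groups + 2))[2:(n_groups + 1)]
  t(vapply(seq_along(idx), function(k) {
    i <- idx[k]
    i2 <- min(i + 1, nrow(rv))
    tang <- rv[i2, ] - rv[max(i - 1, 1), ]
    tang <- tang / sqrt(sum(tang^2))
    nrm <- c(-tang[2], tang[1]) * (if (k %% 2 == 0) 1 else -1)
    c(rx = rv[i, 1], ry = rv[i, 2], nx = nrm[1], ny = nrm[2])
  }, c(rx = 0, ry = 0, nx = 0, ny = 0)))
}

#' Simulate a stationary Ornstein-Uhlenbeck track
#'
#' Discrete-time sampling of an isotropic OU position process with
#' step-to-step correlation `rho = exp(-dt / tau)` and stationary standard
#' deviation `sigma` per axis, started from the stationary distribution.
#'
#' @param n number of positions.
#' @param rho per-step autocorrelation in `[0, 1)`.
#' @param sigma stationary sd per axis (metres).
#' @param centre attraction centre `(x, y)`.
#' @return an `n x 2` matrix of positions.
#' @export
ou_track <- function(n, rho, sigma, centre = c(0, 0)) {
  s_innov <- sigma * sqrt(1 - rho^2)
  one <- function(mu) {
    e <- stats::rnorm(n, 0, s_innov)
    e[1] <- stats::rnorm(1, 0, sigma)
    mu + stats::filter(e, rho, method = "recursive")
  }
  cbind(x = as.numeric(one(centre[1])), y = as.numeric(one(centre[2])))
}

#' Evaluate a group-season's true UD on a grid
#'
#' @param ud_row one row of `ud_params` from [gen_space_use()].
#' @param geom a [grid_geom()].
#' @return a normalized [ud_grid()] (closed-form Gaussian density,
#'   renormalized on the grid).
#' @export
true_ud <- function(ud_row, geom) {
  cc <- cell_centres(geom)
  dx <- stats::dnorm(cc$x, ud_row$mu_x, ud_row$sigma)
  dy <- stats::dnorm(cc$y, ud_row$mu_y, ud_row$sigma)
  v <- outer(dx, dy)
  v <- v / (sum(v) * cell_area(geom))
  ud_grid(grid_raster(v, geom), bandwidth = c(0, 0), n_points = 0L)
}
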