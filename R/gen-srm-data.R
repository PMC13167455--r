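#' Generate directed dyadic overlap data from the hurdle-beta SRM
#'
#' Draws directed proportional-overlap records straight from the social
#' relations model the package fits, with known coefficients: per-group focal
#' and neighbour effects `(g_i, r_i)` jointly bivariate normal with
#' correlation `rho_gr`, per-dyad directed effects `(d_ij, d_ji)` with
#' within-dyad correlation `rho_dd`, shared across the hurdle and beta-mean
#' branches. For each (ordered pair, period): overlap occurs with probability
#' `plogis(eta_h)`; when it occurs, the proportion is Beta with mean
#' `plogis(eta_b)` and precision `phi`. Both directions of every dyad are
#' emitted for every period.
#'
#' @param truth [default_truth()] configuration (`srm` section).
#' @param demography [gen_demography()] table (supplies sizes; one size per
#'   group-period).
#' @param seed integer master seed.
#' @param period `"year"` (annual sizes, no season terms) or `"season-year"`.
#' @return data.frame of directed records: `focal_id`, `neighbour_id`,
#'   `dyad_id`, `period`, `season`, sizes and z-scores, `po`, plus true
#'   effects (`g_focal`, `r_neighbour`, `d_dir`) for recovery oracles.
#' @export
gen_srm_data <- function(truth = default_truth(), demography, seed = 1,
                         period = c("year", "season-year")) {
  period <- match.arg(period)
  cfg <- truth$srm
  Sgr <- matrix(c(cfg$sd_focal^2,
                  cfg$rho_gr * cfg$sd_focal * cfg$sd_neighbour,
                  cfg$rho_gr * cfg$sd_focal * cfg$sd_neighbour,
                  cfg$sd_neighbour^2), 2)
  Sdd <- cfg$sd_dyad^2 * matrix(c(1, cfg$rho_dd, cfg$rho_dd, 1), 2)
  if (any(eigen(Sgr, only.values = TRUE)$values <= 0) ||
      any(eigen(Sdd, only.values = TRUE)$values <= 0))
    stop("implied covariance is not positive definite")
  groups <- sort(unique(demography$group_id))
  sizes <- if (period == "year") {
    agg <- demography[demography$season == "dry",
                      c("group_id", "year", "size", "size_z")]
    transform(agg, period = as.character(year), season = "annual")
  } else {
    transform(demography, period = paste(year, season, sep = "-"))
  }
  with_seed(substream_seed(seed, "srm-data"), {
    gr <- chol_mvn(length(groups), Sgr)
    rownames(gr) <- groups
    pairs <- t(utils::combn(groups, 2))
    dd <- chol_mvn(nrow(pairs), Sdd)
    dyad_ids <- paste(pairs[, 1], pairs[, 2], sep = ":")
    rows <- list()
    for (p in sort(unique(sizes$period))) {
      sz <- sizes[sizes$period == p, ]
      wet <- as.numeric(sz$season[1] == "wet")
      sz_map <- stats::setNames(sz$size_z, sz$group_id)
      n_map <- stats::setNames(sz$size, sz$group_id)
      for (k in seq_len(nrow(pairs))) {
        a <- pairs[k, 1]; b <- pairs[k, 2]
        if (!(a %in% names(sz_map)) || !(b %in% names(sz_map))) next
        for (dir in 1:2) {
          f <- if (dir == 1) a else b
          n <- if (dir == 1) b else a
          fz <- sz_map[f]; nz <- sz_map[n]
          re <- gr[f, 1] + gr[n, 2] + dd[k, dir]
          eta_h <- cfg$hurdle$b0 + cfg$hurdle$b_wet * wet +
            cfg$hurdle$b_focal * fz + cfg$hurdle$b_neighbour * nz +
            cfg$hurdle$b_fn * fz * nz + re
          eta_b <- cfg$mean$b0 + cfg$mean$b_wet * wet +
            cfg$mean$b_focal * fz + cfg$mean$b_neighbour * nz +
            cfg$mean$b_fn * fz * nz + re
          z <- stats::rbinom(1, 1, stats::plogis(eta_h))
          po <- 0
          if (z == 1) {
            mu <- stats::plogis(eta_b)
            po <- stats::rbeta(1, mu * cfg$phi, (1 - mu) * cfg$phi)
            po <- min(max(po, 1e-9), 1 - 1e-9)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            focal_id = f, neighbour_id = n, dyad_id = dyad_ids[k],
            direction = dir, period = p,
            season = sz$season[1], focal_size = n_map[f],
            neighbour_size = n_map[n], focal_size_z = fz,
            neighbour_size_z = nz, po = po,
            g_focal = gr[f, 1], r_neighbour = gr[n, 2], d_dir = dd[k, dir])
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "group_effects") <- gr
    attr(out, "dyad_effects") <- dd
    out
  })
}

chol_mvn <- function(n, Sigma) {
  z <- matrix(stats::rnorm(n * ncol(Sigma)), n)
  z %*% chol(Sigma)
}

#' Generate symmetric encounter-rate data from the multiple-membership model
#'
#' Draws unordered pair-period log encounter rates from the symmetric model
#' the package fits: fixed effects of absolute group-size difference,
#' overlap-zone area and overlap greenness (each z-scored, each interacting
#' with season), a dyad intercept, a multiple-membership group term loading
#' on both members with weight 1, a residual, and known per-row measurement
#' error added on the log scale.
#'
#' @param truth [default_truth()] configuration (`encounter` section).
#' @param demography [gen_demography()] table.
#' @param seed integer master seed.
#' @param pair_fraction fraction of all pairs treated as adjacent (observed).
#' @return data.frame keyed by unordered `pair_id` and season-year `period`
#'   with `log_er_obs`, `log_er_se`, covariates (raw and z-scored) and the
#'   true linear predictor `log_er_true`.
#' @export
gen_encounter_data <- function(truth = default_truth(), demography, seed = 1,
                               pair_fraction = 0.5) {
  cfg <- truth$encounter
  groups <- sort(unique(demography$group_id))
  with_seed(substream_seed(seed, "encounter-data"), {
    u <- stats::setNames(stats::rnorm(length(groups), 0, cfg$sd_group), groups)
    pairs <- t(utils::combn(groups, 2))
    keep <- sort(sample(nrow(pairs), max(2, round(pair_fraction * nrow(pairs)))))
    pairs <- pairs[keep, , drop = FALSE]
    dy <- stats::rnorm(nrow(pairs), 0, cfg$sd_dyad)
    keys <- unique(demography[, c("year", "season")])
    rows <- list()
    for (i in seq_len(nrow(keys))) {
      yr <- keys$year[i]; season <- keys$season[i]
      wet <- as.numeric(season == "wet")
      dem <- demography[demography$year == yr & demography$season == season, ]
      sz <- stats::setNames(dem$size, dem$group_id)
      for (k in seq_len(nrow(pairs))) {
        a <- pairs[k, 1]; b <- pairs[k, 2]
        la <- if (wet == 1) cfg$log_area_mean_wet else cfg$log_area_mean_dry
        nd <- if (wet == 1) cfg$ndvi_mean_wet else cfg$ndvi_mean_dry
        rows[[length(rows) + 1L]] <- data.frame(
          pair_id = paste(a, b, sep = ":"), group_a = a, group_b = b,
          period = paste(yr, season, sep = "-"), year = yr, season = season,
          size_diff_abs = abs(sz[a] - sz[b]),
          overlap_area = exp(stats::rnorm(1, la, cfg$log_area_sd)),
          overlap_ndvi = min(max(stats::rnorm(1, nd, cfg$ndvi_sd), 0.01), 0.95),
          u_a = u[a], u_b = u[b], d = dy[k])
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    z <- function(v) (v - mean(v)) / stats::sd(v)
    sdz <- z(out$size_diff_abs); arz <- z(log(out$overlap_area))
    ndz <- z(out$overlap_ndvi); wet <- as.numeric(out$season == "wet")
    eta <- cfg$b0 + cfg$b_wet * wet +
      (cfg$b_sizediff + cfg$b_sizediff_wet * wet) * sdz +
      (cfg$b_area + cfg$b_area_wet * wet) * arz +
      (cfg$b_ndvi + cfg$b_ndvi_wet * wet) * ndz +
      out$u_a + out$u_b + out$d
    out$size_diff_z <- sdz; out$overlap_area_z <- arz; out$overlap_ndvi_z <- ndz
    out$log_er_true <- eta
    out$log_er_se <- stats::runif(nrow(out), cfg$se_range[1], cfg$se_range[2])
    out$log_er_obs <- eta + stats::rnorm(nrow(out), 0, cfg$sd_resid) +
      stats::rnorm(nrow(out), 0, out$log_er_se)
    out$er <- exp(out$log_er_obs)
    out
  })
}
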