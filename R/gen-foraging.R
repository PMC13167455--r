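#' Generate focal fruit-intake records
#'
#' Bite counts from focal follows are drawn from a negative binomial whose
#' log-mean is `log(seconds_in_view)` (exposure offset) plus the intake linear
#' predictor: baseline rate, wet-season shift, the group-size slope and its
#' season- and anomaly-dependent modifiers
#' (`b_size + b_size_wet * wet + (b_size_spei + b_size_wet_spei * wet) * spei_z`),
#' plus group and individual varying intercepts. With the default truth the
#' size cost is about -0.2 per sd of group size in both seasons, vanishing in
#' abnormally wet dry seasons and worsening to about -0.4 in abnormally dry
#' dry seasons (mirrored in the wet season), which is what the three-way
#' size x season x anomaly interaction in the intake GLMM estimates.
#'
#' @param demography [gen_demography()] table.
#' @param climate [gen_climate()] table.
#' @param truth [default_truth()] configuration (`intake` section).
#' @param seed integer master seed.
#' @param n_per_group_season focal records per group-season (default from
#'   truth).
#' @return data.frame of focal records: ids, season, year, `size_z`, `spei_z`,
#'   `bites`, `seconds_in_view`, `age_sex_class`, and the true log rate
#'   `log_rate_true` for recovery checks.
#' @export
gen_foraging <- function(demography, climate, truth = default_truth(),
                         seed = 1, n_per_group_season = NULL) {
  cfg <- truth$intake
  n_rec <- n_per_group_season %||% cfg$focals_per_group_season
  with_seed(substream_seed(seed, "foraging"), {
    groups <- sort(unique(demography$group_id))
    g_eff <- stats::setNames(stats::rnorm(length(groups), 0, cfg$sd_group),
                             groups)
    ind_pool <- lapply(stats::setNames(groups, groups), function(g) {
      ids <- paste0(g, "-i", sprintf("%02d", 1:30))
      stats::setNames(stats::rnorm(length(ids), 0, cfg$sd_individual), ids)
    })
    rows <- vector("list", nrow(demography))
    classes <- c("adult_female", "adult_male", "subadult", "juvenile")
    for (i in seq_len(nrow(demography))) {
      d <- demography[i, ]
      spei <- climate$spei_z[climate$year == d$year & climate$season == d$season]
      wet <- as.numeric(d$season == "wet")
      ids <- sample(names(ind_pool[[d$group_id]]),
                    min(n_rec, max(2, round(d$size / 2))))
      sec <- stats::runif(length(ids), cfg$seconds_range[1], cfg$seconds_range[2])
      slope <- cfg$b_size + cfg$b_size_wet * wet +
        (cfg$b_size_spei + cfg$b_size_wet_spei * wet) * spei
      eta <- cfg$b0 + cfg$b_wet * wet + cfg$b_spei * spei +
        slope * d$size_z + g_eff[d$group_id] + ind_pool[[d$group_id]][ids]
      bites <- stats::rnbinom(length(ids), size = cfg$dispersion,
                              mu = exp(eta + log(sec)))
      rows[[i]] <- data.frame(
        individual_id = ids, group_id = d$group_id, year = d$year,
        season = d$season, date = sprintf("%d-%02d-15", d$year,
                                          if (wet == 1) 7L else 3L),
        size = d$size, size_z = d$size_z, spei_z = spei, bites = bites,
        seconds_in_view = sec,
        age_sex_class = sample(classes, length(ids), replace = TRUE),
        log_rate_true = eta)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Expected bite count under the intake model
#'
#' The deterministic mean of the negative binomial intake likelihood:
#' `seconds_in_view * exp(eta)`. Exposes the exact offset contract (doubling
#' observation time doubles the expected count).
#'
#' @param eta linear predictor on the log bites-per-second scale.
#' @param seconds_in_view exposure in seconds.
#' @export
intake_mean <- function(eta, seconds_in_view) seconds_in_view * exp(eta)

`%||%` <- function(a, b) if (is.null(a)) b else a
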