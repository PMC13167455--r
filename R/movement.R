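#' Daily path length from a tracked day
#'
#' Mean speed times tracked duration, with mean speed estimated as total
#' summed step length divided by duration at the native sampling interval.
#' Days shorter than the minimum duration (11 h, roughly daylight) are
#' flagged as excluded rather than erroring, matching how short tracking days
#' are screened out of path-length analyses. The SE comes from a moving-block
#' bootstrap over 30-minute blocks of steps, which respects the serial
#' correlation of movement data.
#'
#' @param traj data.frame for one group-day with columns `t` (seconds), `x`,
#'   `y`, sorted by `t`.
#' @param min_hours minimum tracked duration for inclusion.
#' @param block_min bootstrap block length in minutes.
#' @param boot bootstrap replicates (0 = no SE).
#' @return list: `length` (m), `se`, `duration_hours`, `mean_speed` (m/s),
#'   `included`.
#' @export
daily_path_length <- function(traj, min_hours = 11, block_min = 30,
                              boot = 100) {
  stopifnot(all(c("t", "x", "y") %in% names(traj)))
  traj <- traj[!duplicated(traj$t), ]
  if (is.unsorted(traj$t, strictly = TRUE)) traj <- traj[order(traj$t), ]
  dur_h <- (max(traj$t) - min(traj$t)) / 3600
  steps <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  len <- sum(steps)
  out <- list(length = len, se = NA_real_, duration_hours = dur_h,
              mean_speed = if (dur_h > 0) len / (dur_h * 3600) else 0,
              included = dur_h >= min_hours)
  if (!out$included || boot == 0 || length(steps) < 4) return(out)
  step_t <- traj$t[-1]
  blocks <- split(seq_along(steps),
                  floor((step_t - min(step_t)) / (block_min * 60)))
  blocks <- blocks[lengths(blocks) > 0]
  bl <- vapply(seq_len(boot), function(b) {
    pick <- sample(length(blocks), length(blocks), replace = TRUE)
    tot <- sum(vapply(blocks[pick], function(ix) sum(steps[ix]), 0))
    tot
  }, 0)
  out$se <- stats::sd(bl)
  out
}

#' Mean revisitation rate of a utilization distribution
#'
#' Continuous-time revisitation: the local rate at a point is the product of
#' the mean speed and the UD density there, and averaging that surface over
#' the UD itself gives `rate = radius * speed * integral(p(x)^2 dx)` -- the
#' expected frequency of returns to a neighbourhood of radial size `radius`.
#' The rate is defined per metre of radius and scales exactly linearly, so it
#' can be rescaled to any radius (e.g. 25-50 m) after the fact.
#'
#' @param ud a [ud_grid()].
#' @param mean_speed mean movement speed (m/s, > 0).
#' @param radius radial scale in metres.
#' @return revisitation rate (returns per second, per `radius` metres).
#' @export
revisitation_rate <- function(ud, mean_speed, radius = 1) {
  if (!is.finite(mean_speed) || mean_speed <= 0) stop("mean_speed must be > 0")
  radius * mean_speed * sum(ud$values^2) * cell_area(ud$geom)
}
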