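#' Specify the symmetric multiple-membership encounter model
#'
#' The response is the log encounter rate with a known per-row measurement
#' SE (Gaussian on the log scale, marginalized into the observation
#' variance). Fixed effects are the three symmetric dyadic predictors --
#' absolute group-size difference, overlap-zone area (log) and overlap
#' greenness -- each z-scored internally and, in seasonal specs, interacted
#' with season. Varying effects are a dyad intercept and a group term that
#' loads on *both* member groups with weight 1, so the linear predictor is
#' exactly invariant to swapping the two group labels within a row.
#'
#' @param seasonal include season main effect and season x predictor
#'   interactions.
#' @export
mm_spec <- function(seasonal = TRUE) {
  structure(list(seasonal = seasonal), class = "mm_spec")
}

mm_design <- function(spec, records) {
  z <- function(v) (v - mean(v)) / stats::sd(v)
  sdz <- z(records$size_diff_abs)
  arz <- z(log(records$overlap_area))
  ndz <- z(records$overlap_ndvi)
  cols <- list(intercept = rep(1, nrow(records)))
  if (spec$seasonal) {
    wet <- as.numeric(records$season == "wet")
    cols$wet <- wet
    cols$size_diff <- sdz; cols$overlap_area <- arz; cols$overlap_ndvi <- ndz
    cols[["size_diff:wet"]] <- sdz * wet
    cols[["overlap_area:wet"]] <- arz * wet
    cols[["overlap_ndvi:wet"]] <- ndz * wet
  } else {
    cols$size_diff <- sdz; cols$overlap_area <- arz; cols$overlap_ndvi <- ndz
  }
  scales <- rbind(size_diff = c(mean(records$size_diff_abs),
                                stats::sd(records$size_diff_abs)),
                  overlap_area = c(mean(log(records$overlap_area)),
                                   stats::sd(log(records$overlap_area))),
                  overlap_ndvi = c(mean(records$overlap_ndvi),
                                   stats::sd(records$overlap_ndvi)))
  colnames(scales) <- c("mean", "sd")
  list(X = do.call(cbind, cols), scales = scales)
}

#' Fit the multiple-membership encounter model
#'
#' @param spec an [mm_spec()].
#' @param records unordered pair-period rows with `group_a`, `group_b`,
#'   `pair_id`, `season`, covariates `size_diff_abs`, `overlap_area`,
#'   `overlap_ndvi`, response `log_er_obs` (or `er`) and its SE `log_er_se`.
#' @param mcmc an [mcmc_config()].
#' @param seed integer seed.
#' @return object of class `rc_mm` with named coefficient draws, `sd_group`,
#'   `sd_dyad`, `sd_resid`.
#' @export
fit_encounter_mm <- function(spec, records, mcmc = mcmc_config(), seed = 1) {
  y <- records$log_er_obs %||% log(records$er)
  se <- records$log_er_se
  if (any(!is.finite(y))) stop("encounter rates must be positive and finite")
  if (is.null(se) || any(!is.finite(se)) || any(se <= 0))
    stop("per-row SEs of the log encounter rate must be positive")
  des <- mm_design(spec, records)
  groups <- sort(unique(c(records$group_a, records$group_b)))
  dyads <- sort(unique(records$pair_id))
  jd <- list(N = nrow(records), K = ncol(des$X), X = des$X, y = y,
             se2 = se^2,
             ga = match(records$group_a, groups),
             gb = match(records$group_b, groups),
             dy = match(records$pair_id, dyads),
             G = length(groups), D = length(dyads))
  code <- '
model {
  for (i in 1:N) {
    mu[i] <- inprod(X[i, ], b[]) + (u[ga[i]] + u[gb[i]]) + d[dy[i]]
    tau_y[i] <- 1 / (pow(sd_resid, 2) + se2[i])
    y[i] ~ dnorm(mu[i], tau_y[i])
  }
  b[1] ~ dnorm(0, 0.04)
  for (k in 2:K) { b[k] ~ dnorm(0, 1) }
  for (g in 1:G) { u[g] ~ dnorm(0, tau_u) }
  for (j in 1:D) { d[j] ~ dnorm(0, tau_d) }
  mu_re <- 2 * mean(u[]) + mean(d[])
  sd_group ~ dnorm(0, 1) T(0, )
  sd_dyad ~ dnorm(0, 1) T(0, )
  sd_resid ~ dnorm(0, 1) T(0, )
  tau_u <- pow(sd_group, -2)
  tau_d <- pow(sd_dyad, -2)
}'
  fit <- run_jags(code, jd, c("b", "sd_group", "sd_dyad", "sd_resid"),
                  mcmc, seed, recenter = list("b[1]" = c(mu_re = 1)))
  nm <- colnames(fit$draws)
  bcols <- grepl("^b\\[", nm)
  nm[bcols] <- colnames(des$X)[as.integer(sub("^b\\[(\\d+)\\]$", "\\1",
                                              nm[bcols]))]
  colnames(fit$draws) <- nm
  out <- structure(list(draws = fit$draws, spec = spec,
                        rhat_max = fit$rhat_max, ess_min = fit$ess_min,
                        n = nrow(records), scales = des$scales),
                   class = "rc_mm")
  check_convergence(fit)
  out
}

#' @export
print.rc_mm <- function(x, ...) {
  cat(sprintf("<rc_mm> n = %d pair-periods, max R-hat = %s\n", x$n,
              ifelse(is.na(x$rhat_max), "NA", sprintf("%.3f", x$rhat_max))))
  print(summarize_draws(x$draws))
  invisible(x)
}

#' Wet-minus-dry contrast of a dyadic predictor's slope
#'
#' In the seasonal multiple-membership model the wet - dry difference of a
#' predictor's slope is its season-interaction coefficient; this summarizes
#' those draws (negative values mean the predictor bites harder in the dry
#' season).
#'
#' @param fit an [fit_encounter_mm()] result.
#' @param term one of `"size_diff"`, `"overlap_area"`, `"overlap_ndvi"`.
#' @return a [posterior_summary()] row.
#' @export
season_slope_contrast <- function(fit, term = c("overlap_area", "size_diff",
                                                "overlap_ndvi")) {
  term <- match.arg(term)
  if (!fit$spec$seasonal) stop("seasonal contrast needs a seasonal model")
  col <- paste0(term, ":wet")
  posterior_summary(fit$draws[, col],
                    sprintf("wet_minus_dry[%s]", term), rhat = fit$rhat_max)
}
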