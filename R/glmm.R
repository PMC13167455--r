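#' Specify a group-level GLMM
#'
#' Maps each response to its likelihood family: negative binomial for focal
#' intake counts (with a log observation-time offset), gamma for daily path
#' length, revisitation rate and home-range area (the latter two optionally
#' with measurement error), and beta for mean home-range NDVI. Fixed effects
#' are the z-scored group size, season, their interaction, and optionally the
#' full three-way interaction with the standardized seasonal climate anomaly.
#' All models carry a group varying intercept; intake adds an individual
#' intercept and home-range NDVI a year intercept.
#'
#' @param response one of `"intake"`, `"dpl"`, `"revisitation"`, `"hra"`,
#'   `"hr_ndvi"`.
#' @param response_col data column holding the response (default per
#'   response).
#' @param seasonal include season and size x season terms.
#' @param spei include the three-way size x season x anomaly interaction
#'   (requires `seasonal = TRUE`).
#' @param offset_col column with exposure (seconds in view); entered as a log
#'   offset. Only meaningful for count responses.
#' @param se_col column with known per-row SE of the log response
#'   (measurement-error model; gamma family only).
#' @return list of class `glmm_spec`.
#' @export
group_model_spec <- function(response = c("intake", "dpl", "revisitation",
                                          "hra", "hr_ndvi"),
                             response_col = NULL, seasonal = TRUE,
                             spei = FALSE, offset_col = NULL, se_col = NULL) {
  response <- match.arg(response)
  family <- switch(response, intake = "negative_binomial",
                   hr_ndvi = "beta", "gamma")
  if (spei && !seasonal)
    stop("the three-way anomaly interaction requires a seasonal model")
  if (!is.null(se_col) && family != "gamma")
    stop("measurement error on the response is supported for gamma responses")
  extra_varying <- switch(response, intake = "individual_id",
                          hr_ndvi = "year", NULL)
  if (is.null(response_col))
    response_col <- switch(response, intake = "bites", dpl = "dpl",
                           revisitation = "revisit", hra = "area",
                           hr_ndvi = "mean_ndvi")
  if (response == "intake" && is.null(offset_col))
    offset_col <- "seconds_in_view"
  structure(list(response = response, family = family,
                 response_col = response_col, seasonal = seasonal,
                 spei = spei, offset_col = offset_col, se_col = se_col,
                 extra_varying = extra_varying),
            class = "glmm_spec")
}

glmm_design <- function(spec, data) {
  data$season <- factor(data$season, levels = c("dry", "wet"))
  fml <- if (!spec$seasonal) ~size_z
  else if (!spec$spei) ~ size_z * season
  else ~ size_z * season * spei_z
  X <- stats::model.matrix(fml, data)
  list(X = X, data = data)
}

#' Fit a group-level Bayesian GLMM with JAGS
#'
#' Priors are weakly regularizing: Normal(0, 1) on standardized-scale slopes,
#' Normal(0, 5) on intercepts (which may sit far from zero on offset scales),
#' half-Normal(0, 1) on varying-effect standard deviations and Normal(0, 2.5)
#' on log shape/precision/dispersion parameters. Convergence is gated at
#' split R-hat < 1.01 on all monitored parameters (a warning flags
#' violations). Beta responses at exactly 0 or 1 are nudged inward by 1e-6
#' and the number of nudged rows is recorded on the fit.
#'
#' @param spec a [group_model_spec()].
#' @param data data.frame with `size_z`, `season`, `group_id`, the response
#'   column, and as needed `spei_z`, the offset/SE columns and the extra
#'   varying-intercept column.
#' @param mcmc a [mcmc_config()].
#' @param seed integer seed.
#' @return object of class `rc_glmm`: `draws` (named columns `b[...]` mapped
#'   to design-matrix names), `coef_names`, `spec`, `rhat_max`, `ess_min`,
#'   `n`, `n_nudged`, `size_scale`.
#' @export
fit_group_glmm <- function(spec, data, mcmc = mcmc_config(), seed = 1) {
  des <- glmm_design(spec, data)
  X <- des$X; data <- des$data
  y <- data[[spec$response_col]]
  if (anyNA(X) || anyNA(y)) stop("missing values in model variables")
  group <- as.integer(factor(data$group_id))
  jd <- list(N = nrow(X), K = ncol(X), X = X, group = group,
             G = max(group))
  monitors <- c("b", "sd_group")
  n_nudged <- 0L
  lik <- switch(spec$family,
    negative_binomial = {
      jd$y <- as.integer(y)
      jd$off <- if (!is.null(spec$offset_col)) log(data[[spec$offset_col]])
                else rep(0, nrow(X))
      monitors <- c(monitors, "r_disp")
      paste("y[i] ~ dnegbin(pnb[i], r_disp)",
            "pnb[i] <- r_disp / (r_disp + mu[i])",
            "log(mu[i]) <- eta[i] + off[i]", sep = "\n    ")
    },
    gamma = {
      if (any(y <= 0)) stop("gamma responses must be positive")
      monitors <- c(monitors, "shape")
      if (is.null(spec$se_col)) {
        jd$y <- y
        paste("y[i] ~ dgamma(shape, shape / mu[i])",
              "log(mu[i]) <- eta[i]", sep = "\n    ")
      } else {
        se <- data[[spec$se_col]]
        if (any(!is.finite(se)) || any(se <= 0))
          stop("measurement-error SEs must be positive")
        jd$logy <- log(y); jd$tau_obs <- se^-2
        paste("lat[i] ~ dgamma(shape, shape / mu[i])",
              "logy[i] ~ dnorm(log(lat[i]), tau_obs[i])",
              "log(mu[i]) <- eta[i]", sep = "\n    ")
      }
    },
    beta = {
      n_nudged <- sum(y <= 0 | y >= 1)
      y <- pmin(pmax(y, 1e-6), 1 - 1e-6)
      jd$y <- y
      monitors <- c(monitors, "phi")
      paste("y[i] ~ dbeta(mu[i] * phi, (1 - mu[i]) * phi)",
            "logit(mu[i]) <- eta[i]", sep = "\n    ")
    })
  extra <- ""
  if (!is.null(spec$extra_varying)) {
    v2 <- as.integer(factor(data[[spec$extra_varying]]))
    jd$v2 <- v2; jd$V2 <- max(v2)
    extra <- " + u2[v2[i]]"
    monitors <- c(monitors, "sd_u2")
  }
  scale_prior <- switch(spec$family,
                        negative_binomial = "r_disp <- exp(log_scale)",
                        gamma = "shape <- exp(log_scale)",
                        beta = "phi <- exp(log_scale)")
  code <- sprintf('
model {
  for (i in 1:N) {
    eta[i] <- inprod(X[i, ], b[]) + u_group[group[i]]%s
    %s
  }
  b[1] ~ dnorm(0, 0.04)
  for (k in 2:K) { b[k] ~ dnorm(0, 1) }
  for (g in 1:G) { u_group[g] ~ dnorm(0, tau_group) }
  mu_ug <- mean(u_group[])
  sd_group ~ dnorm(0, 1) T(0, )
  tau_group <- pow(sd_group, -2)
  %s
  log_scale ~ dnorm(0, 0.16)
  %s
}', extra, lik, scale_prior,
    if (nzchar(extra))
      paste("for (v in 1:V2) { u2[v] ~ dnorm(0, tau_u2) }",
            "mu_u2 <- mean(u2[])",
            "sd_u2 ~ dnorm(0, 1) T(0, )",
            "tau_u2 <- pow(sd_u2, -2)", sep = "\n  ")
    else "")
  recenter_terms <- if (nzchar(extra)) c(mu_ug = 1, mu_u2 = 1) else c(mu_ug = 1)
  inits_extra <- if (!is.null(jd$logy)) list(lat = exp(jd$logy)) else NULL
  fit <- run_jags(code, jd, monitors, mcmc, seed,
                  recenter = list("b[1]" = recenter_terms),
                  inits_extra = inits_extra)
  nm <- colnames(fit$draws)
  bcols <- grepl("^b\\[", nm)
  nm[bcols] <- colnames(X)[as.integer(sub("^b\\[(\\d+)\\]$", "\\1", nm[bcols]))]
  colnames(fit$draws) <- nm
  out <- structure(list(draws = fit$draws, coef_names = colnames(X),
                        spec = spec, rhat_max = fit$rhat_max,
                        ess_min = fit$ess_min, n = nrow(X),
                        n_nudged = n_nudged,
                        size_scale = c(mean = attr(data, "size_mean") %||% NA,
                                       sd = attr(data, "size_sd") %||% NA)),
                   class = "rc_glmm")
  check_convergence(fit)
  out
}

#' @export
print.rc_glmm <- function(x, ...) {
  cat(sprintf("<rc_glmm> %s (%s), n = %d, max R-hat = %s\n", x$spec$response,
              x$spec$family, x$n,
              ifelse(is.na(x$rhat_max), "NA", sprintf("%.3f", x$rhat_max))))
  print(summarize_draws(x$draws[, x$coef_names, drop = FALSE]))
  invisible(x)
}

coef_draws <- function(fit, name) {
  if (name %in% colnames(fit$draws)) fit$draws[, name] else
    rep(0, nrow(fit$draws))
}

#' Marginal (conditional) group-size slope
#'
#' Per-draw linear combination of the interaction terms giving the size slope
#' in a given season at a given anomaly value; used to read off e.g. the
#' dry-season slope at representative anomalies -1.5, 0, +1.5.
#'
#' @param fit an [fit_group_glmm()] result.
#' @param season `"dry"`, `"wet"`, or `"annual"` (non-seasonal model).
#' @param spei_z anomaly value the slope is conditioned on.
#' @param label estimand label for the summary.
#' @return a [posterior_summary()] row.
#' @export
marginal_slope <- function(fit, season = "dry", spei_z = 0, label = NULL) {
  d <- marginal_slope_draws(fit, season, spei_z)
  posterior_summary(d, label %||%
                      sprintf("size_slope[%s, spei=%g]", season, spei_z),
                    rhat = fit$rhat_max)
}

marginal_slope_draws <- function(fit, season, spei_z = 0) {
  wet <- as.numeric(identical(season, "wet"))
  coef_draws(fit, "size_z") +
    wet * coef_draws(fit, "size_z:seasonwet") +
    spei_z * (coef_draws(fit, "size_z:spei_z") +
                wet * coef_draws(fit, "size_z:seasonwet:spei_z"))
}

#' Wet-minus-dry posterior contrast
#'
#' @param fit an [fit_group_glmm()] result.
#' @param estimand `"size_slope"` (difference of seasonal size slopes) or
#'   `"season_effect"` (the wet-season intercept shift).
#' @param spei_z anomaly value at which slopes are contrasted.
#' @return a [posterior_summary()] row for the per-draw wet - dry difference.
#' @export
seasonal_contrast <- function(fit, estimand = c("size_slope", "season_effect"),
                              spei_z = 0) {
  estimand <- match.arg(estimand)
  d <- if (estimand == "size_slope")
    marginal_slope_draws(fit, "wet", spei_z) -
      marginal_slope_draws(fit, "dry", spei_z)
  else coef_draws(fit, "seasonwet") + spei_z * coef_draws(fit, "seasonwet:spei_z")
  posterior_summary(d, sprintf("wet_minus_dry[%s]", estimand),
                    rhat = fit$rhat_max)
}
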