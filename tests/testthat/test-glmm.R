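# One moderately sized seeded intake fit is shared across several checks.
intake_fit_cache <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      tr <- default_truth()
      dem <- gen_demography(10, 2008:2023, tr, seed = 55)
      cl <- gen_climate(2008:2023, tr, seed = 55)
      fr <- gen_foraging(dem, cl, tr, seed = 55, n_per_group_season = 3)
      fit <<- fit_group_glmm(group_model_spec("intake", spei = TRUE), fr,
                             fast_mcmc(), seed = 55)
    }
    fit
  }
})

test_that("the intake GLMM recovers the generative size effect", {
  fit <- intake_fit_cache()
  ms <- marginal_slope(fit, "dry", spei_z = 0)
  expect_lt(abs(ms$median + 0.2), 0.2)
  expect_lt(ms$pp_gt0, 0.2)
  expect_true(all(c("size_z", "size_z:seasonwet:spei_z", "r_disp",
                    "sd_group", "sd_u2") %in% colnames(fit$draws)))
})

test_that("conditional slopes are an exact linear identity per draw", {
  fit <- intake_fit_cache()
  s_lo <- marginal_slope_draws(fit, "dry", -1.5)
  s_0 <- marginal_slope_draws(fit, "dry", 0)
  s_hi <- marginal_slope_draws(fit, "dry", 1.5)
  expect_equal(s_0, (s_lo + s_hi) / 2, tolerance = 1e-12)
  # wet - dry contrast is antisymmetric by construction per draw
  cw <- marginal_slope_draws(fit, "wet", 0) - marginal_slope_draws(fit, "dry", 0)
  expect_equal(seasonal_contrast(fit, "size_slope")$median, median(cw))
})

test_that("a model without interactions gives one slope at all anomalies", {
  tr <- default_truth()
  dem <- gen_demography(6, 2014:2023, tr, seed = 56)
  cl <- gen_climate(2014:2023, tr, seed = 56)
  fr <- gen_foraging(dem, cl, tr, seed = 56, n_per_group_season = 2)
  fit <- fit_group_glmm(group_model_spec("intake", seasonal = FALSE), fr,
                        fast_mcmc(iter = 200), seed = 56)
  expect_identical(marginal_slope_draws(fit, "dry", -1.5),
                   marginal_slope_draws(fit, "dry", 1.5))
})

test_that("measurement error vanishing recovers the error-free gamma fit", {
  tr <- default_truth()
  set.seed(57)
  n <- 240
  dat <- data.frame(group_id = rep(sprintf("g%02d", 1:8), each = 30),
                    season = rep(c("dry", "wet"), n / 2),
                    size_z = rnorm(n))
  dat$area <- exp(log(2e6) + 0.3 * dat$size_z +
                    0.25 * (dat$season == "wet") + rnorm(n, 0, 0.2))
  dat$se_tiny <- 1e-4
  f0 <- fit_group_glmm(group_model_spec("hra", response_col = "area"), dat,
                       fast_mcmc(), seed = 57)
  f1 <- fit_group_glmm(group_model_spec("hra", response_col = "area",
                                        se_col = "se_tiny"), dat,
                       fast_mcmc(), seed = 57)
  s0 <- marginal_slope(f0, "dry")$median
  s1 <- marginal_slope(f1, "dry")$median
  expect_lt(abs(s0 - s1), 0.05)
  expect_lt(abs(s0 - 0.3), 0.1)
})

test_that("beta responses at the boundary are nudged and counted", {
  set.seed(58)
  n <- 120
  dat <- data.frame(group_id = rep(sprintf("g%02d", 1:6), each = 20),
                    year = rep(2011:2020, 12),
                    season = rep(c("dry", "wet"), n / 2),
                    size_z = rnorm(n),
                    mean_ndvi = c(0, 1, runif(n - 2, 0.3, 0.7)))
  fit <- fit_group_glmm(group_model_spec("hr_ndvi"), dat,
                        fast_mcmc(iter = 150), seed = 58)
  expect_equal(fit$n_nudged, 2L)
})

test_that("model specification guards its family and term contracts", {
  expect_error(group_model_spec("intake", seasonal = FALSE, spei = TRUE),
               "seasonal")
  expect_error(group_model_spec("intake", se_col = "se"), "gamma")
  expect_identical(group_model_spec("hr_ndvi")$family, "beta")
  expect_identical(group_model_spec("dpl")$family, "gamma")
  expect_identical(group_model_spec("intake")$family, "negative_binomial")
  expect_error(fit_group_glmm(group_model_spec("hra"),
                              data.frame(group_id = "a", season = "dry",
                                         size_z = 0, area = -1),
                              fast_mcmc(), 1), "positive")
})
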