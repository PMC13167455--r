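land_fix <- function() gen_landscape(list(nx = 60, ny = 60), seed = 8)

test_that("true range areas encode the configured size slope", {
  tr <- default_truth()
  dem <- gen_demography(10, 1991:2010, tr, seed = 21)     # 400 group-seasons
  cl <- gen_climate(1991:2010, tr, seed = 21)
  su <- gen_space_use(dem, land_fix(), cl, tr, seed = 21, n_days = 0)
  expect_gte(nrow(su$ud_params), 200)
  slope <- coef(lm(log(area95_true) ~ size_z + season, su$ud_params))["size_z"]
  expect_lt(abs(unname(slope) - 0.3), 0.05)
})

test_that("a null size slope is recovered as null", {
  tr <- default_truth(space_use = list(b_size_hra = 0))
  dem <- gen_demography(10, 1991:2010, tr, seed = 22)
  cl <- gen_climate(1991:2010, tr, seed = 22)
  su <- gen_space_use(dem, land_fix(), cl, tr, seed = 22, n_days = 0)
  slope <- coef(lm(log(area95_true) ~ size_z + season, su$ud_params))["size_z"]
  expect_lt(abs(unname(slope)), 0.05)
})

test_that("OU tracks are stationary with the requested spread", {
  set.seed(5)
  x <- ou_track(1e5, rho = exp(-5 / 30), sigma = 250, centre = c(10, -20))
  expect_equal(sd(x[, 1]), 250, tolerance = 0.05 * 250)
  expect_equal(sd(x[, 2]), 250, tolerance = 0.05 * 250)
  expect_equal(mean(x[, 1]), 10, tolerance = 25)
  r1 <- cor(x[-1, 1], x[-1e5, 1])
  expect_equal(r1, exp(-5 / 30), tolerance = 0.03)
})

test_that("trajectories are time-ordered and sleep sites daily", {
  tr <- default_truth()
  dem <- tiny_demography(3, 2019:2021)
  cl <- tiny_climate(2019:2021)
  su <- gen_space_use(dem, land_fix(), cl, tr, seed = 2, n_days = 2)
  by_day <- split(su$trajectories$t,
                  paste(su$trajectories$group_id, su$trajectories$date))
  expect_true(all(vapply(by_day, function(t) !is.unsorted(t, strictly = TRUE),
                         TRUE)))
  expect_equal(nrow(su$sleep_sites), 3 * 3 * 2 * 2)
})

test_that("group-seasons with missing sizes are skipped with a warning", {
  tr <- default_truth()
  dem <- tiny_demography(3, 2019:2021)
  dem$size[3] <- NA
  cl <- tiny_climate(2019:2021)
  expect_warning(su <- gen_space_use(dem, land_fix(), cl, tr, seed = 2,
                                     n_days = 0), "missing")
  expect_equal(nrow(su$ud_params), nrow(dem) - 1)
})

test_that("dry-season centres sit nearer the river for larger groups", {
  tr <- default_truth()
  dem <- gen_demography(12, 1991:2010, tr, seed = 23)
  cl <- gen_climate(1991:2010, tr, seed = 23)
  land <- land_fix()
  su <- gen_space_use(dem, land, cl, tr, seed = 23, n_days = 0)
  up <- su$ud_params[su$ud_params$season == "dry", ]
  d <- vapply(seq_len(nrow(up)), function(i)
    min(sqrt((land$river[, 1] - up$mu_x[i])^2 +
               (land$river[, 2] - up$mu_y[i])^2)), 0)
  expect_lt(cor(d, up$size_z), 0)
})
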