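test_that("fitted UDs are normalized probability surfaces", {
  set.seed(71)
  g <- grid_geom(c(-1500, -1500), 30, 100, 100)
  pts <- cbind(rnorm(500, 0, 200), rnorm(500, 0, 200))
  ud <- fit_ud(pts, g)
  expect_equal(sum(ud$values) * cell_area(g), 1, tolerance = 1e-6)
  expect_true(all(ud$values >= 0))
  expect_equal(ud$n_points, 500L)
})

test_that("UDs are equivariant under whole-cell translations", {
  set.seed(72)
  g <- grid_geom(c(0, 0), 30, 80, 80)
  pts <- cbind(runif(200, 600, 1000), runif(200, 600, 1000))
  ud1 <- fit_ud(pts, g)
  shift <- c(10 * 30, -4 * 30)
  ud2 <- fit_ud(sweep(pts, 2, -shift), g)
  # compare the overlapping interior blocks
  expect_equal(ud1$values[1:60, 20:80], ud2$values[11:70, 16:76],
               tolerance = 1e-9)
})

test_that("a Gaussian cloud recovers its centre and 95% contour area", {
  set.seed(73)
  sigma <- 300
  g <- grid_geom(c(-2500, -2500), 30, 167, 167)
  pts <- cbind(rnorm(6e4, 0, sigma), rnorm(6e4, 0, sigma))
  ud <- fit_ud(pts, g, keep_points = FALSE)
  hr <- hr_contour(ud, 0.95)
  expect_lt(max(abs(hr$centroid)), 0.02 * sigma)
  expect_equal(hr$area, pi * sigma^2 * qchisq(0.95, 2),
               tolerance = 0.10 * pi * sigma^2 * qchisq(0.95, 2))
  hr98 <- hr_contour(ud, 0.98)
  expect_gte(hr98$area, hr$area)
  expect_true(all(hr$cells %in% hr98$cells))
})

test_that("uniform UDs give contours of proportional area", {
  geom <- grid_geom(c(0, 0), 10, 50, 40)
  ud <- uniform_ud(geom)
  hr <- hr_contour(ud, 0.95)
  total <- 50 * 40 * cell_area(geom)
  expect_equal(hr$area, 0.95 * total, tolerance = cell_area(geom) * 60)
})

test_that("degenerate point sets are rejected", {
  g <- grid_geom(c(0, 0), 30, 60, 60)
  expect_error(fit_ud(cbind(rep(1, 50), rep(2, 50)), g), "bandwidth|coincid")
  expect_error(fit_ud(cbind(1:5, 1:5), g), "20")
})

test_that("the KDE agrees with an independent reference implementation", {
  set.seed(74)
  pts <- cbind(rnorm(400, 0, 150), rnorm(400, 50, 150))
  g <- grid_geom(c(-1000, -1000), 20, 101, 101)
  cc <- cell_centres(g)
  h <- rangecomp:::silverman_bw(pts)
  ref <- MASS::kde2d(pts[, 1], pts[, 2], h = 4 * h, n = 101,
                     lims = c(range(cc$x), range(cc$y)))
  ud <- fit_ud(pts, g)
  ref_density <- ref$z / (sum(ref$z) * cell_area(g))
  expect_equal(max(abs(ud$values - ref_density)), 0, tolerance = 1e-10)
})

test_that("bootstrap area SEs are positive and sane", {
  set.seed(75)
  g <- grid_geom(c(-1500, -1500), 30, 100, 100)
  pts <- cbind(rnorm(300, 0, 200), rnorm(300, 0, 200))
  hr <- hr_contour(fit_ud(pts, g), 0.95, boot = 8)
  expect_gt(hr$se, 0)
  expect_lt(hr$se, hr$area)
})
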