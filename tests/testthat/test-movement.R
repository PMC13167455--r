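test_that("constant-speed motion returns speed times duration exactly", {
  t <- seq(0, 11 * 3600, by = 30)
  traj <- data.frame(t = t, x = t * 1.0, y = 0)
  dp <- daily_path_length(traj, boot = 0)
  expect_true(dp$included)
  expect_equal(dp$length, 39600, tolerance = 0.01 * 39600)
  expect_equal(dp$mean_speed, 1, tolerance = 0.01)
})

test_that("stationary tracks have zero path length; short days are flagged", {
  t <- seq(0, 12 * 3600, by = 60)
  expect_equal(daily_path_length(data.frame(t = t, x = 5, y = -3),
                                 boot = 0)$length, 0)
  short <- data.frame(t = seq(0, 3600 * 5, 60), x = rnorm(301), y = rnorm(301))
  dp <- daily_path_length(short, boot = 0)
  expect_false(dp$included)
})

test_that("block-bootstrap SEs exist for included days", {
  set.seed(81)
  x <- ou_track(1321, rho = exp(-0.5 / 30), sigma = 250)
  traj <- data.frame(t = seq(0, by = 30, length.out = 1321),
                     x = x[, 1], y = x[, 2])
  dp <- daily_path_length(traj, boot = 50)
  expect_true(dp$included)
  expect_gt(dp$se, 0)
})

test_that("path length estimates are stable under subsampling a smooth path", {
  # a path that is smooth at the sampling scale (curvature timescale of
  # hours) loses little length when thinned from 30 s to 5 min fixes;
  # summed step length is not robust for paths that are tortuous at the
  # fix interval, which is why tracking data at the native resolution is
  # used throughout
  t <- seq(0, 11 * 3600, by = 30)
  R <- 2000; omega <- 2 * pi / (2 * 3600)  # one lap every two hours
  traj <- data.frame(t = t, x = R * sin(omega * t), y = R * cos(omega * t))
  fine <- daily_path_length(traj, boot = 0)
  coarse <- daily_path_length(traj[seq(1, nrow(traj), by = 10), ], boot = 0)
  expect_equal(fine$length, R * omega * 11 * 3600, tolerance = 0.01 * fine$length)
  expect_lt(abs(coarse$length - fine$length) / fine$length, 0.10)
})

test_that("revisitation scales linearly in radius and matches closed forms", {
  ud <- gaussian_ud(sigma = 300)
  r1 <- revisitation_rate(ud, 0.5, radius = 1)
  expect_identical(revisitation_rate(ud, 0.5, radius = 50), 50 * r1)
  expect_equal(r1, 0.5 / (4 * pi * 300^2), tolerance = 0.01 * r1)
  geom <- grid_geom(c(0, 0), 10, 50, 50)
  uu <- uniform_ud(geom)
  A <- 500 * 500
  expect_equal(revisitation_rate(uu, 2, radius = 25), 25 * 2 / A,
               tolerance = 1e-12)
  expect_error(revisitation_rate(ud, 0), "> 0")
})
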