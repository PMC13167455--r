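test_that("HPDIs are shortest intervals of the requested mass", {
  set.seed(111)
  u <- runif(1e5)
  iv <- hpdi(u, 0.89)
  expect_equal(unname(iv["hi"] - iv["lo"]), 0.89, tolerance = 0.02)
  # symmetric unimodal: HPDI close to the equal-tailed interval
  z <- rnorm(1e5)
  hz <- hpdi(z, 0.89)
  qz <- quantile(z, c(0.055, 0.945))
  expect_equal(unname(hz), unname(qz), tolerance = 0.05)
  # skewed samples: HPDI strictly shorter than equal-tailed
  s <- rexp(1e5)
  hs <- hpdi(s, 0.89)
  qs <- quantile(s, c(0.055, 0.945))
  expect_lt(hs["hi"] - hs["lo"], qs[2] - qs[1])
  expect_identical(unname(hpdi(rep(3.2, 100), 0.89)), c(3.2, 3.2))
})

test_that("posterior summaries report median, interval and sign mass", {
  set.seed(112)
  x <- rnorm(4000, 1, 1)
  ps <- posterior_summary(x, "beta")
  expect_equal(ps$median, median(x))
  expect_true(ps$lo <= ps$median && ps$median <= ps$hi)
  expect_equal(ps$pp_gt0, mean(x > 0))
  expect_equal(ps$estimand, "beta")
})

test_that("hurdle-beta log densities match hand formulas", {
  expect_equal(hurdle_beta_loglik(0, theta = 0.3, mu = 0.5, phi = 4),
               log(0.3), ignore_attr = TRUE, tolerance = 1e-12)
  # Beta(2, 2) density at 0.5 is 1.5
  expect_equal(hurdle_beta_loglik(0.5, theta = 0.3, mu = 0.5, phi = 4),
               log(0.7) + log(1.5), ignore_attr = TRUE, tolerance = 1e-12)
  ll <- hurdle_beta_loglik(c(0, 0.25, 1), 0.2, 0.4, 8)
  expect_equal(attr(ll, "n_shrunk"), 1)
  expect_true(all(is.finite(ll)))
  # total probability mass is one
  dens <- function(x) exp(hurdle_beta_loglik(x, 0.3, 0.6, 5))
  mass <- 0.3 + integrate(dens, 1e-12, 1 - 1e-12, rel.tol = 1e-10)$value
  expect_equal(mass, 1, tolerance = 1e-8)
  # order invariance of the joint log likelihood
  set.seed(113)
  po <- c(rep(0, 20), rbeta(80, 2, 3))
  perm <- sample(100)
  expect_equal(sum(hurdle_beta_loglik(po, 0.2, 0.4, 6)),
               sum(hurdle_beta_loglik(po[perm], 0.2, 0.4, 6)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(hurdle_beta_loglik(0.5, theta = 1.2, mu = 0.5, phi = 2))
})
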