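test_that("with effects silenced, zeros occur at exactly the hurdle rate", {
  tr <- default_truth(srm = list(sd_focal = 1e-6, sd_neighbour = 1e-6,
                                 sd_dyad = 1e-6,
                                 hurdle = list(b0 = qlogis(0.7), b_focal = 0,
                                               b_neighbour = 0, b_fn = 0),
                                 mean = list(b0 = -1, b_focal = 0,
                                             b_neighbour = 0, b_fn = 0),
                                 phi = 200))
  dem <- gen_demography(12, 1974:2023, tr, seed = 41)   # 66*2*50 = 6600 draws
  d <- gen_srm_data(tr, dem, seed = 41)
  n <- nrow(d)
  expect_gte(n, 1e4 * 0.6)
  p_hat <- mean(d$po > 0)
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(p_hat - 0.7), 2 * se + 1e-3)
  # all nonzero draws share one beta mean
  expect_equal(mean(d$po[d$po > 0]), plogis(-1), tolerance = 0.01)
})

test_that("within-dyad correlation of directed effects is as configured", {
  tr <- default_truth(srm = list(rho_dd = 0.9))
  dem <- gen_demography(12, 2023, tr, seed = 42)
  reps <- lapply(1:31, function(k) attr(gen_srm_data(tr, dem, seed = k),
                                        "dyad_effects"))
  dd <- do.call(rbind, reps)     # > 2000 dyads
  expect_gte(nrow(dd), 2000)
  expect_gt(cor(dd[, 1], dd[, 2]), 0.85)
  expect_lt(cor(dd[, 1], dd[, 2]), 0.95)
})

test_that("the neighbour-size slope is recoverable on the logit scale", {
  tr <- default_truth(srm = list(sd_focal = 1e-6, sd_neighbour = 1e-6,
                                 sd_dyad = 1e-6, phi = 400,
                                 hurdle = list(b0 = 5, b_focal = 0,
                                               b_neighbour = 0, b_fn = 0),
                                 mean = list(b0 = -1, b_focal = 0,
                                             b_neighbour = 0.5, b_fn = 0)))
  dem <- gen_demography(12, 1994:2023, tr, seed = 43)
  d <- gen_srm_data(tr, dem, seed = 43)
  d <- d[d$po > 0, ]
  fit <- lm(qlogis(po) ~ focal_size_z + neighbour_size_z, d)
  expect_equal(unname(coef(fit)["neighbour_size_z"]), 0.5, tolerance = 0.1)
})

test_that("directed records are complete, bounded, and double-entered", {
  tr <- default_truth()
  dem <- tiny_demography(5, 2019:2021)
  d <- gen_srm_data(tr, dem, seed = 44)
  expect_true(all(d$po >= 0 & d$po < 1))
  key <- paste(d$dyad_id, d$period)
  expect_true(all(table(key) == 2))
  ok <- tapply(seq_len(nrow(d)), key, function(ix)
    d$focal_id[ix[1]] == d$neighbour_id[ix[2]] &&
      d$neighbour_id[ix[1]] == d$focal_id[ix[2]])
  expect_true(all(unlist(ok)))
  expect_identical(d, gen_srm_data(tr, dem, seed = 44))
  # degenerate correlation structure rejected
  expect_error(gen_srm_data(default_truth(srm = list(rho_dd = 1)), dem, 1),
               "positive definite|correlations")
})

test_that("encounter records are symmetric in construction and reproducible", {
  tr <- default_truth()
  dem <- tiny_demography(6, 2018:2021)
  e <- gen_encounter_data(tr, dem, seed = 45)
  expect_true(all(e$er > 0))
  expect_true(all(e$log_er_se > 0))
  expect_true(all(e$size_diff_abs >= 0))
  expect_identical(e, gen_encounter_data(tr, dem, seed = 45))
})
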