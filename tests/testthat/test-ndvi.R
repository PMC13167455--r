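test_that("NDVI follows its defining ratio and mask contract", {
  g <- grid_geom(c(0, 0), 30, 3, 3)
  red <- const_raster(0.2, g)
  nir <- const_raster(0.6, g)
  expect_equal(compute_ndvi(red, nir)$values[1, 1], 0.5)
  expect_equal(compute_ndvi(red, const_raster(0.2, g))$values[2, 2], 0)
  qa <- grid_raster(matrix(c(TRUE, rep(FALSE, 8)), 3, 3), g)
  masked <- compute_ndvi(red, nir, qa)
  expect_true(is.na(masked$values[1, 1]))
  expect_equal(sum(is.na(masked$values)), 1)
  zero <- const_raster(0, g)
  expect_true(all(is.na(compute_ndvi(zero, zero)$values)))
  g2 <- grid_geom(c(0, 0), 30, 4, 3)
  expect_error(compute_ndvi(red, const_raster(0.6, g2)), "match")
  expect_error(compute_ndvi(const_raster(-0.1, g), nir), ">= 0")
})

test_that("maximum composites skip missing values and are idempotent", {
  g <- grid_geom(c(0, 0), 30, 2, 2)
  r1 <- grid_raster(matrix(c(0.2, NA, 0.1, NA), 2, 2), g)
  r2 <- grid_raster(matrix(c(NA, NA, 0.5, 0.3), 2, 2), g)
  r3 <- grid_raster(matrix(c(0.5, NA, 0.2, NA), 2, 2), g)
  cm <- max_composite(list(r1, r2, r3))
  expect_equal(cm$values, matrix(c(0.5, NA, 0.5, 0.3), 2, 2))
  expect_identical(max_composite(list(r1))$values, r1$values)
  # composite dominates every input where both defined; idempotent
  expect_identical(max_composite(list(cm, cm))$values, cm$values)
  for (r in list(r1, r2, r3)) {
    both <- !is.na(r$values) & !is.na(cm$values)
    expect_true(all(cm$values[both] >= r$values[both]))
  }
  expect_error(max_composite(list()), "empty")
})

test_that("zonal means use the cell-centre rule and match a full scan", {
  g <- grid_geom(c(0, 0), 10, 12, 12)
  hr <- hr_from_predicate(g, function(x, y) x < 47 & y < 33)
  expect_equal(mean_raster_in_range(const_raster(0.42, g), hr)$mean, 0.42)
  # two known cells
  v <- matrix(0, 12, 12); v[1, 1] <- 0.2; v[2, 1] <- 0.4
  two <- hr_from_predicate(g, function(x, y) y < 10 & x < 20)
  expect_equal(mean_raster_in_range(grid_raster(v, g), two)$mean, 0.3)
  expect_equal(mean_raster_in_range(grid_raster(v, g), two)$n_cells, 2)
  # brute-force oracle on a random raster / random polygonal predicate
  set.seed(1)
  rr <- grid_raster(matrix(runif(144), 12, 12), g)
  rr$values[sample(144, 20)] <- NA
  pred <- function(x, y) (x - 60)^2 + (y - 50)^2 < 45^2
  hr2 <- hr_from_predicate(g, pred)
  cc <- cell_centres(g)
  acc <- n <- 0
  for (ix in 1:12) for (iy in 1:12) {
    if (pred(cc$x[ix], cc$y[iy]) && !is.na(rr$values[ix, iy])) {
      acc <- acc + rr$values[ix, iy]; n <- n + 1
    }
  }
  got <- mean_raster_in_range(rr, hr2)
  expect_equal(got$mean, acc / n, tolerance = 1e-12)
  expect_equal(got$n_cells, n)
  # all cells masked inside -> reject
  rr$values[hr2$cells] <- NA
  expect_error(mean_raster_in_range(rr, hr2), "unmasked")
})
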