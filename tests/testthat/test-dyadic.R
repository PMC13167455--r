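disc_hr <- function(centre, r, geom) {
  hr_from_predicate(geom, function(x, y)
    (x - centre[1])^2 + (y - centre[2])^2 <= r^2)
}

test_that("proportional overlap obeys its identity and disjoint limits", {
  g <- grid_geom(c(0, 0), 5, 120, 120)
  A <- disc_hr(c(150, 300), 80, g)
  B <- disc_hr(c(450, 300), 80, g)
  expect_equal(proportional_overlap(A, A)$po, 1)
  expect_equal(proportional_overlap(A, B)$po, 0)
  expect_equal(proportional_overlap(B, A)$po, 0)
})

test_that("two-disc overlap matches the circular-lens closed form", {
  g <- grid_geom(c(-3.2, -4), 0.008, 1100, 1000)
  A <- disc_hr(c(0, 0), 2, g)
  B <- disc_hr(c(2, 0), 2, g)
  lens <- 8 * acos(0.5) - sqrt(12)
  ab <- proportional_overlap(A, B)
  ba <- proportional_overlap(B, A)
  expect_equal(ab$po, lens / (4 * pi), tolerance = 0.005 * lens / (4 * pi))
  expect_equal(ba$po, lens / (4 * pi), tolerance = 0.005 * lens / (4 * pi))
  expect_identical(ab$ia, ba$ia)
})

test_that("intersection areas are symmetric across the double entry", {
  set.seed(91)
  g <- grid_geom(c(-1500, -1500), 30, 100, 100)
  for (k in 1:5) {
    hA <- hr_contour(fit_ud(cbind(rnorm(200, runif(1, -400, 400), 250),
                                  rnorm(200, runif(1, -400, 400), 250)), g),
                     0.95)
    hB <- hr_contour(fit_ud(cbind(rnorm(200, runif(1, -400, 400), 250),
                                  rnorm(200, runif(1, -400, 400), 250)), g),
                     0.95)
    ab <- proportional_overlap(hA, hB)
    ba <- proportional_overlap(hB, hA)
    expect_equal(ab$po * ab$hra_focal, ba$po * ba$hra_focal,
                 tolerance = 1e-6 * max(ab$ia, 1))
    expect_true(ab$po >= 0 && ab$po <= 1)
  }
})

test_that("overlap zones handle disjoint, nested and generic cases", {
  g <- grid_geom(c(0, 0), 5, 120, 120)
  A <- disc_hr(c(200, 300), 100, g)
  inner <- disc_hr(c(200, 300), 40, g)
  far <- disc_hr(c(500, 100), 40, g)
  z0 <- overlap_zone(A, far)
  expect_equal(z0$area, 0)
  expect_true(is.na(z0$mean_ndvi))
  zn <- overlap_zone(A, inner)
  expect_setequal(zn$cells, inner$cells)
  # area agrees with a brute-force scan of both membership predicates
  B <- disc_hr(c(280, 300), 100, g)
  z <- overlap_zone(A, B, const_raster(0.37, g))
  cc <- cell_centres(g)
  n_brute <- 0
  for (ix in 1:120) for (iy in 1:120) {
    x <- cc$x[ix]; y <- cc$y[iy]
    if ((x - 200)^2 + (y - 300)^2 <= 100^2 &&
        (x - 280)^2 + (y - 300)^2 <= 100^2) n_brute <- n_brute + 1
  }
  expect_equal(z$area, n_brute * cell_area(g))
  expect_equal(z$mean_ndvi, 0.37)
})

test_that("grid encounter rates match the Gaussian closed form", {
  g <- grid_geom(c(-3000, -3000), 30, 200, 200)
  u1 <- gaussian_ud(c(0, 0), 300, g)
  u2 <- gaussian_ud(c(400, 0), 300, g)
  er <- encounter_rate(u1, u2)$er
  ref <- encounter_rate_gaussian(c(0, 0), c(400, 0), 300, 300)
  expect_equal(er, ref, tolerance = 0.01 * ref)
  # identical UDs: self-overlap 1/(4 pi sigma^2)
  expect_equal(encounter_rate(u1, u1)$er, 1 / (4 * pi * 300^2),
               tolerance = 0.01 / (4 * pi * 300^2))
  # widely separated ranges: essentially zero
  u3 <- gaussian_ud(c(3000, 2800), 100, g)
  expect_lt(encounter_rate(gaussian_ud(c(-2800, -2800), 100, g), u3)$er,
            1e-11)
  # exact symmetry, bit for bit
  expect_identical(encounter_rate(u1, u2)$er, encounter_rate(u2, u1)$er)
  g2 <- grid_geom(c(0, 0), 30, 200, 200)
  expect_error(encounter_rate(u1, gaussian_ud(c(0, 0), 300, g2)), "grid")
})

test_that("encounter-rate bootstrap SEs require and use retained points", {
  set.seed(92)
  g <- grid_geom(c(-1500, -1500), 30, 100, 100)
  uA <- fit_ud(cbind(rnorm(150, 0, 200), rnorm(150, 0, 200)), g)
  uB <- fit_ud(cbind(rnorm(150, 150, 200), rnorm(150, 0, 200)), g)
  er <- encounter_rate(uA, uB, boot = 8)
  expect_gt(er$se, 0)
  expect_gt(er$log_se, 0)
})

test_that("centroid-shift distances behave like plane geometry", {
  mk <- function(centroid) structure(list(cells = 1L,
                                          centroid = c(x = centroid[1],
                                                       y = centroid[2])),
                                     class = "home_range")
  zone <- function(centroid) list(cells = 1L,
                                  centroid = c(x = centroid[1],
                                               y = centroid[2]))
  hr <- mk(c(0, 0))
  expect_equal(delta_d(hr, zone(c(100, 0)), zone(c(100, 0))), 0)
  expect_equal(delta_d(hr, zone(c(100, 0)), zone(c(300, 0))), 200)
  # rigid rotation about an arbitrary point leaves delta_d unchanged
  set.seed(93)
  p <- matrix(rnorm(6, 0, 500), 3, 2)
  th <- runif(1, 0, 2 * pi); pivot <- rnorm(2, 0, 300)
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(v) as.numeric(Rm %*% (v - pivot) + pivot)
  d1 <- delta_d(mk(p[1, ]), zone(p[2, ]), zone(p[3, ]))
  d2 <- delta_d(mk(rot(p[1, ])), zone(rot(p[2, ])), zone(rot(p[3, ])))
  expect_equal(d1, d2, tolerance = 1e-9)
  expect_error(delta_d(hr, list(cells = integer(0), centroid = c(NA, NA)),
                       zone(c(1, 1))), "non-empty")
})

test_that("directed dyad tables are double-entered with matching areas", {
  g <- grid_geom(c(0, 0), 10, 80, 80)
  ranges <- list(a = disc_hr(c(300, 400), 150, g),
                 b = disc_hr(c(450, 400), 150, g),
                 c = disc_hr(c(300, 650), 120, g))
  dt <- directed_dyad_table(ranges, "2020", c(a = 10, b = 25, c = 15))
  expect_equal(nrow(dt), 6)
  for (dy in unique(dt$dyad_id)) {
    two <- dt[dt$dyad_id == dy, ]
    expect_identical(two$ia[1], two$ia[2])
    expect_equal(two$po[1], two$ia[1] / two$hra_focal[1], tolerance = 1e-9)
  }
})
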