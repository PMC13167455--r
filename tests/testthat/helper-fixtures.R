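# Shared fixtures: built in code, deterministic, small.

tiny_demography <- function(n_groups = 4, years = 2018:2023, seed = 11,
                            truth = default_truth()) {
  gen_demography(n_groups, years, truth, seed)
}

tiny_climate <- function(years = 2018:2023, seed = 11) {
  gen_climate(years, default_truth(), seed)
}

# constant-valued raster on a small grid
const_raster <- function(value, geom = grid_geom(c(0, 0), 10, 12, 12)) {
  grid_raster(matrix(value, geom$nx, geom$ny), geom)
}

# exact Gaussian UD evaluated on a grid (closed form, renormalized)
gaussian_ud <- function(mu = c(0, 0), sigma = 300,
                        geom = grid_geom(c(-3000, -3000), 30, 200, 200)) {
  true_ud(data.frame(mu_x = mu[1], mu_y = mu[2], sigma = sigma), geom)
}

# uniform UD over the full grid
uniform_ud <- function(geom = grid_geom(c(0, 0), 10, 50, 50)) {
  a <- geom$nx * geom$ny * cell_area(geom)
  ud_grid(grid_raster(matrix(1 / a, geom$nx, geom$ny), geom),
          bandwidth = c(0, 0), n_points = 0L)
}

fast_mcmc <- function(chains = 1, adapt = 200, warmup = 150, iter = 300) {
  mcmc_config(chains = chains, adapt = adapt, warmup = warmup, iter = iter)
}
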