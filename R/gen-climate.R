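#' Generate a synthetic seasonal climate-anomaly series
#'
#' Produces one water-balance anomaly value per year-season as an AR(1)
#' process over the alternating dry/wet season sequence (dry = January-April,
#' wet = May-December), mimicking the temporal persistence of ENSO-linked
#' drought indices. Raw anomalies are then standardized within season via
#' [standardize_spei()], so `spei_z` measures deviation from typical
#' conditions *for that season*: negative = abnormally dry, positive =
#' abnormally wet.
#'
#' @param years integer vector of at least 3 years.
#' @param truth a [default_truth()] configuration (uses `climate$ar`,
#'   `climate$innov_sd`).
#' @param seed integer master seed.
#' @return data.frame with `year`, `season`, `spei_raw`, `spei_z`.
#' @export
gen_climate <- function(years, truth = default_truth(), seed = 1) {
  if (length(years) < 3) stop("need at least 3 years to standardize within season")
  ar <- truth$climate$ar
  with_seed(substream_seed(seed, "climate"), {
    n <- 2L * length(years)
    innov <- stats::rnorm(n, 0, truth$climate$innov_sd)
    x <- numeric(n)
    x[1] <- innov[1] / sqrt(max(1 - ar^2, 1e-12))  # stationary start
    for (i in 2:n) x[i] <- ar * x[i - 1] + sqrt(1 - ar^2) * innov[i]
    out <- data.frame(year = rep(years, each = 2),
                      season = rep(c("dry", "wet"), times = length(years)),
                      spei_raw = x)
    standardize_spei(out)
  })
}
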