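#' Ground-truth parameters of the synthetic study system
#'
#' Every downstream model in the package estimates quantities that this
#' configuration generates, so parameter recovery can be checked against known
#' values. Coefficients are on the scale the corresponding model estimates:
#' z-scored group size, log/logit links, dry season as the reference level and
#' `wet` terms as wet-minus-dry differences.
#'
#' The defaults emulate the study system the package targets: 10-13 capuchin
#' groups of 5-40 individuals (population mean about 18.8) followed for about
#' three decades on a seasonal riparian landscape. Larger groups ingest less
#' fruit per capita (strongest under seasonally extreme climate anomalies),
#' hold larger home ranges, revisit less, and in wet dry seasons occupy
#' greener ranges; neighbour size increases directed overlap most when the
#' focal group is small; encounter rate rises with overlap-zone area and
#' greenness, more steeply in the dry season.
#'
#' @param ... named overrides of any default entry (matched by full path name,
#'   e.g. `intake = list(b_size = -0.1)` replaces only that entry).
#' @return a nested list of class `generative_truth`.
#' @export
default_truth <- function(...) {
  truth <- list(
    demography = list(
      size_init_mean = 18.8, size_init_sd = 7, walk_sd = 1.4,
      size_min = 5, size_max = 40, fission = FALSE, fission_rate = 0.01),
    climate = list(ar = 0.6, innov_sd = 1),
    landscape = list(
      ndvi_rip_dry = 0.45, ndvi_bg_dry = 0.22, decay_dry = 350,
      ndvi_rip_wet = 0.12, ndvi_bg_wet = 0.6, decay_wet = 1200,
      image_noise_sd = 0.03, haze_sd = 0.06, qa_fraction = 0.12,
      n_images = 3, reflectance_sum = 0.5),
    space_use = list(
      log_area_dry = log(1.6e6),      # dry-season 95% area (m^2) at mean size
      b_size_hra = 0.3,               # log-area slope on size_z
      b_wet_hra = 0.25,               # wet ranges larger
      area_noise_sd = 0.18,
      riparian_d0 = 900,              # wet-season centre distance to river (m)
      riparian_dry = 350,             # dry-season baseline centre distance (m)
      placement_pull = 0.45,          # size pull toward the river, dry season
      placement_spei_mod = 2 / 3,     # pull scales with (1 + mod * spei_z)
      centre_jitter_sd = 120,
      tau_min = 30,                   # OU range-crossing timescale (minutes)
      speed_scale = 1,                # multiplies implied OU speed
      n_components = 1),
    intake = list(
      b0 = log(30 / 3600),            # bites per second in view at baseline
      b_wet = 0.25, b_size = -0.2, b_spei = 0.05,
      b_size_wet = 0, b_wet_spei = 0,
      b_size_spei = 0.1333,           # dry: slope ~0 at spei +1.5, worst at -1.5
      b_size_wet_spei = -0.2667,      # wet: slope worst at spei +1.5
      dispersion = 2, sd_group = 0.2, sd_individual = 0.3,
      focals_per_group_season = 4, seconds_range = c(600, 3600)),
    srm = list(
      hurdle = list(b0 = 0.8, b_wet = 0.5, b_focal = -0.3, b_neighbour = 0.5,
                    b_fn = -0.2),
      mean = list(b0 = -1.6, b_wet = 0.35, b_focal = -0.25, b_neighbour = 0.5,
                  b_fn = -0.3),
      phi = 12,
      sd_focal = 0.4, sd_neighbour = 0.3, sd_dyad = 0.5,
      rho_gr = 0.3, rho_dd = 0.8),
    encounter = list(
      b0 = -6, b_wet = -0.6,
      b_sizediff = 0, b_area = 0.9, b_ndvi = 0.42,
      b_sizediff_wet = 0, b_area_wet = -0.5, b_ndvi_wet = -0.27,
      sd_group = 0.3, sd_dyad = 0.4, sd_resid = 0.3,
      se_range = c(0.05, 0.2),
      log_area_mean_dry = log(2e5), log_area_mean_wet = log(4e5),
      log_area_sd = 0.6, ndvi_mean_dry = 0.45, ndvi_mean_wet = 0.62,
      ndvi_sd = 0.06)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(truth)) stop("unknown truth section: ", nm)
    if (is.list(ov[[nm]])) truth[[nm]] <- utils::modifyList(truth[[nm]], ov[[nm]])
    else truth[[nm]] <- ov[[nm]]
  }
  validate_truth(structure(truth, class = "generative_truth"))
}

validate_truth <- function(truth) {
  sds <- c(truth$srm$sd_focal, truth$srm$sd_neighbour, truth$srm$sd_dyad,
           truth$encounter$sd_group, truth$encounter$sd_dyad,
           truth$encounter$sd_resid)
  if (any(sds <= 0)) stop("all standard deviations must be > 0")
  if (abs(truth$srm$rho_gr) >= 1 || abs(truth$srm$rho_dd) >= 1)
    stop("correlations must lie in (-1, 1)")
  if (truth$srm$phi <= 0) stop("beta precision must be > 0")
  truth
}

#' Serialize / restore a truth configuration
#'
#' Round-trips the full configuration through plain-text YAML so any run is
#' reproducible from (config file, seed).
#'
#' @param truth a [default_truth()] object.
#' @param path file path ending in `.yml`/`.yaml`.
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(unclass(truth), path, precision = 15)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  validate_truth(structure(yaml::read_yaml(path), class = "generative_truth"))
}
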