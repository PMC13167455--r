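#' Generate synthetic group demography
#'
#' Simulates yearly group sizes for `n_groups` social groups as independent
#' bounded integer random walks, then expands each year into a dry
#' (January-April) and wet (May-December) season record. Sizes are constrained
#' to the configured bounds (5-40 by default, population mean near 18.8).
#' Optional fission events split off a daughter group that keeps a reduced
#' size; fissions relabel demography only (no spatial inheritance).
#'
#' @param n_groups number of groups (>= 2).
#' @param years integer vector of study years.
#' @param truth a [default_truth()] configuration.
#' @param seed integer master seed (fans out via [substream_seed()]).
#' @return data.frame with columns `group_id`, `year`, `season`, `size`,
#'   `size_z`; attributes `size_mean`/`size_sd` store the z-scoring used.
#' @export
gen_demography <- function(n_groups = 12, years = 1991:2023,
                           truth = default_truth(), seed = 1) {
  if (n_groups < 2) stop("n_groups must be >= 2")
  if (length(years) == 0) stop("years must be non-empty")
  cfg <- truth$demography
  with_seed(substream_seed(seed, "demography"), {
    rows <- list()
    next_id <- n_groups + 1L
    for (g in seq_len(n_groups)) {
      gid <- sprintf("g%02d", g)
      size <- round(stats::rnorm(1, cfg$size_init_mean, cfg$size_init_sd))
      size <- min(max(size, cfg$size_min), cfg$size_max)
      sizes <- numeric(length(years))
      for (t in seq_along(years)) {
        if (t > 1) {
          step <- if (cfg$walk_sd > 0) round(stats::rnorm(1, 0, cfg$walk_sd)) else 0
          size <- min(max(size + step, cfg$size_min), cfg$size_max)
        }
        sizes[t] <- size
        if (isTRUE(cfg$fission) && size >= 30 &&
            stats::runif(1) < cfg$fission_rate && t < length(years)) {
          keep <- ceiling(size * 0.6)
          daughter <- size - keep
          if (daughter >= cfg$size_min) {
            did <- sprintf("g%02d", next_id); next_id <- next_id + 1L
            dsz <- rw_tail(daughter, length(years) - t, cfg)
            rows[[length(rows) + 1L]] <-
              data.frame(group_id = did, year = years[(t + 1):length(years)],
                         size = dsz)
            size <- keep
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(group_id = gid, year = years,
                                              size = sizes)
    }
    ann <- do.call(rbind, rows)
    out <- rbind(transform(ann, season = "dry"), transform(ann, season = "wet"))
    out <- out[order(out$group_id, out$year, out$season), ]
    rownames(out) <- NULL
    out$size_z <- as.numeric(scale(out$size))
    attr(out, "size_mean") <- mean(out$size)
    attr(out, "size_sd") <- stats::sd(out$size)
    out[, c("group_id", "year", "season", "size", "size_z")]
  })
}

rw_tail <- function(size, n, cfg) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    step <- if (cfg$walk_sd > 0) round(stats::rnorm(1, 0, cfg$walk_sd)) else 0
    size <- min(max(size + step, cfg$size_min), cfg$size_max)
    out[i] <- size
  }
  out
}
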