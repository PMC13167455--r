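#' Highest posterior density interval
#'
#' Shortest contiguous interval of the sorted samples containing `mass` of
#' the draws. Effect summaries throughout the package use 89% HPDIs, a
#' deliberately non-canonical mass that discourages reading intervals as
#' significance tests.
#'
#' @param samples numeric vector of posterior draws.
#' @param mass interval probability mass in (0, 1).
#' @return named numeric `c(lo, hi)`.
#' @export
hpdi <- function(samples, mass = 0.89) {
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n == 0) stop("no finite samples")
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(lo = x[1], hi = x[n]))
  width <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(width)
  c(lo = x[i], hi = x[i + k])
}

#' Summarize a scalar estimand's posterior draws
#'
#' @param samples numeric vector (or single-column matrix) of draws.
#' @param label estimand name.
#' @param mass HPDI mass.
#' @param rhat,ess optional convergence diagnostics to attach.
#' @return one-row data.frame: `estimand`, `median`, `lo`, `hi`, `pp_gt0`,
#'   `rhat`, `ess`.
#' @export
posterior_summary <- function(samples, label = "estimand", mass = 0.89,
                              rhat = NA_real_, ess = NA_real_) {
  s <- as.numeric(samples)
  iv <- hpdi(s, mass)
  data.frame(estimand = label, median = stats::median(s),
             lo = iv[["lo"]], hi = iv[["hi"]],
             pp_gt0 = mean(s > 0), rhat = rhat, ess = ess,
             row.names = NULL)
}

#' Summarize every column of a draws matrix
#'
#' @param draws matrix of posterior draws (columns = parameters).
#' @param mass HPDI mass.
#' @export
summarize_draws <- function(draws, mass = 0.89) {
  do.call(rbind, lapply(colnames(draws), function(p)
    posterior_summary(draws[, p], p, mass)))
}
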