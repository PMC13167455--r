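#' Derive a reproducible substream seed from a master seed and a layer name
#'
#' One master integer seed fans out to independent per-layer substreams by
#' stable string hashing, so that e.g. the climate series does not change when
#' the demography layer draws a different number of random variates. The hash
#' is a plain polynomial rolling hash over the UTF-8 bytes of `layer`, folded
#' with the master seed modulo 2^31 - 1; it involves no R RNG state.
#'
#' @param seed master integer seed.
#' @param layer character scalar naming the substream.
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
substream_seed <- function(seed, layer) {
  stopifnot(length(layer) == 1, is.character(layer))
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(layer)) h <- (h * 131 + b) %% m
  h <- (h * 69069 + (as.numeric(seed) %% m) * 40503 + 12345) %% m
  as.integer(h %% (m - 2) + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
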