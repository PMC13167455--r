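# Shared setup for the numbered analysis scripts.
# Run each script from the repository root, e.g.
#   Rscript analysis/01_simulate.R
#
# Each script computes the pipeline stages it needs and caches stage output
# under scratch/ (not part of the deliverable) so later scripts reuse it.
# All tables land in results/. Set RANGECOMP_SEED to change the scenario seed.

suppressMessages({
  if (requireNamespace("rangecomp", quietly = TRUE)) {
    library(rangecomp)
  } else {
    devtools::load_all(".", quiet = TRUE)   # running from a source checkout
  }
})

SEED <- as.integer(Sys.getenv("RANGECOMP_SEED", "1"))
CFG <- run_config(seed = SEED)
RESULTS <- "results"
CACHE <- file.path("scratch", "analysis_cache")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)
dir.create(CACHE, showWarnings = FALSE, recursive = TRUE)

cache_path <- function(stage) file.path(CACHE, sprintf("%s_%d.rds", stage, SEED))

get_stage <- function(stage, producer) {
  p <- cache_path(stage)
  if (file.exists(p)) return(readRDS(p))
  x <- producer()
  saveRDS(x, p)
  x
}

banner <- function(...) cat("\n==", sprintf(...), "==\n")
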