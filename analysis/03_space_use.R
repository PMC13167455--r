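#!/usr/bin/env Rscript
# Estimate utilization distributions, home ranges, range greenness, daily
# path lengths and revisitation rates for every group-season, and summarize
# how they scale with group size.

source("analysis/00_common.R")

banner("space-use metrics (seed %d)", SEED)
data <- get_stage("generate", function() rangecomp:::stage_generate(CFG))
metrics <- get_stage("metrics", function()
  rangecomp:::stage_metrics(CFG, data))

seas <- metrics$seasonal
write.csv(seas, file.path(RESULTS, "group_season_metrics.csv"),
          row.names = FALSE)
write.csv(metrics$daily, file.path(RESULTS, "daily_path_lengths.csv"),
          row.names = FALSE)

cat(sprintf("estimated %d group-season ranges (95%% level)\n", nrow(seas)))
cat(sprintf("area: median %.2f km2; naive log-area ~ size_z slope %.2f (truth %.2f)\n",
            median(seas$area) / 1e6,
            coef(lm(log(area) ~ size_z + season, seas))["size_z"],
            CFG$truth$space_use$b_size_hra))
cat(sprintf("range NDVI: dry %.3f vs wet %.3f\n",
            mean(seas$mean_ndvi[seas$season == "dry"], na.rm = TRUE),
            mean(seas$mean_ndvi[seas$season == "wet"], na.rm = TRUE)))
dpl <- metrics$daily[metrics$daily$included, ]
cat(sprintf("daily path length: %d usable days, median %.1f km\n",
            nrow(dpl), median(dpl$dpl) / 1000))
cat(sprintf("revisitation (25 m): median %.2e returns/s\n",
            median(seas$revisit)))

# one exported example range
hr1 <- metrics$annual_hr[[1]][[1]]
if (!is.null(hr1))
  write_hr_geojson(hr1, file.path(RESULTS, "example_home_range.geojson"))
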