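#!/usr/bin/env Rscript
# Occurrence-record distance analysis against the epoch-A habitat network:
# research-grade filtering, per-record distance to the nearest patch or
# corridor, the 200-point random null, and a record-density heatmap with a
# compact 5 km influence radius (scaled here to 1 km on the toy extent).

library(habnet)

fix_dir <- file.path("results", "fixtures")
lc <- read_landcover(file.path(fix_dir, "landcover_epoch_a.asc"),
                     default_legend())
occ <- read_occurrences(file.path(fix_dir, "occurrences.csv"))
occ <- filter_records(occ, exclude_taxa = c("Ovis aries", "Equus caballus"))

rg <- burn_linear_features(
  landcover_resistance(lc),
  read_linear_features(file.path(fix_dir, "infrastructure.geojson")))
ps <- extract_patches(lc, min_area = 20 * 900)
g <- build_graph(ps, cost_distance(rg, ps), theta = 5000)
paths <- edge_paths(rg, ps, g)

obs <- distance_to_network(occ, ps, paths)
null <- random_null(lc$grid, n = 200, seed = 20260105, ps, paths)

heat <- record_heatmap(occ, lc$grid, radius = 1000)
write_ascii <- habnet:::write_ascii_grid
write_ascii(heat, lc$grid, file.path("results", "record_heatmap.asc"))

write.csv(data.frame(n = obs$n, mean_m = obs$mean, median_m = obs$median,
                     max_m = obs$max, null_mean_m = null$null_mean,
                     null_n = null$null_n, null_seed = null$seed),
          file.path("results", "occurrence_distances.csv"),
          row.names = FALSE)

cat(sprintf("records analysed: %d (research grade)\n", obs$n))
cat(sprintf("mean distance to patch/path: %.2f m (median %.2f, max %.2f)\n",
            obs$mean, obs$median, obs$max))
cat(sprintf("random-point null mean:      %.2f m (n = %d)\n",
            null$null_mean, null$null_n))
cat(sprintf("observed records sit %.2f m closer to the network than random\n",
            null$null_mean - obs$mean))
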