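#!/usr/bin/env Rscript
# Simulate the study inputs: a two-epoch 30 m land-cover raster pair
# (epoch B converts 10% of farmland to hardwoods, emulating a decade of
# rural abandonment and native-forest expansion), linear infrastructure,
# and habitat-attracted occurrence records. Everything is written as
# plain-text geodata under results/fixtures/ for the downstream scripts.

library(habnet)

fix_dir <- file.path("results", "fixtures")
dir.create(fix_dir, recursive = TRUE, showWarnings = FALSE)

spec <- landscape_spec(n_rows = 80, n_cols = 80, seed = 20260101,
                       n_occurrences = 60, attraction = 0.8)
lc_a <- generate_landcover(spec)
lc_b <- perturb_epoch(lc_a,
                      data.frame(from = "agricultural/herbaceous",
                                 to = "hardwoods", fraction = 0.10),
                      seed = 20260102)
feats <- generate_infrastructure(spec)
occ <- generate_occurrences(spec, lc_a)

write_landcover(lc_a, file.path(fix_dir, "landcover_epoch_a.asc"))
write_landcover(lc_b, file.path(fix_dir, "landcover_epoch_b.asc"))
write_linear_features(feats, file.path(fix_dir, "infrastructure.geojson"))
write.csv(data.frame(x = occ$x, y = occ$y, taxon = occ$taxon,
                     observed_on = occ$date,
                     quality_grade = occ$quality_grade),
          file.path(fix_dir, "occurrences.csv"), row.names = FALSE)

tab_a <- tabulate_cover(lc_a)
tab_b <- tabulate_cover(lc_b)
cat("epoch A composition (%):\n")
print(setNames(round(tab_a$share_pct, 2), tab_a$class))
cat("epoch B hardwood share:",
    round(tab_b$share_pct[tab_b$class == "hardwoods"], 2), "%\n")
cat("fixtures written to", fix_dir, "\n")
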