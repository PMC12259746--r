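#!/usr/bin/env Rscript
# Accuracy assessment of a (simulated) classification: sparse validation
# cells are sampled from the epoch-A map, classification noise is injected
# at a known rate, and the confusion matrix, per-class commission/omission,
# overall accuracy and Cohen's kappa are computed. With 5% label noise the
# expected accuracy is about 0.95.

library(habnet)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

lc <- read_landcover(file.path("results", "fixtures",
                               "landcover_epoch_a.asc"), default_legend())

set.seed(20260103)
n_cells <- lc$grid$n_rows * lc$grid$n_cols
n_val <- round(0.0031 * n_cells) * 10  # ~3% of cells as validation pixels
val_cells <- sample(which(!is.na(lc$codes)), n_val)

predicted <- lc$codes
noise <- runif(n_val) < 0.05
codes_pool <- as.integer(names(default_legend()))
predicted[val_cells[noise]] <- vapply(predicted[val_cells[noise]],
  function(code) sample(setdiff(codes_pool, code), 1L), integer(1))
pred_lc <- hab_landcover(predicted, lc$grid, lc$legend)

val_codes <- matrix(NA_integer_, lc$grid$n_rows, lc$grid$n_cols)
val_codes[val_cells] <- lc$codes[val_cells]
val_lc <- hab_landcover(val_codes, lc$grid, lc$legend)

cm <- build_confusion(pred_lc, val_lc, classes = unname(default_legend()))
metrics <- suppressWarnings(accuracy_metrics(cm))
write_confusion(cm, file.path(out_dir, "confusion_matrix.csv"))
write.csv(metrics$per_class, file.path(out_dir, "class_errors.csv"),
          row.names = FALSE)

cat(sprintf("validation cells: %d (%.2f%% of the raster)\n", cm$N,
            100 * cm$N / n_cells))
cat(sprintf("overall accuracy: %.4f\n", metrics$accuracy))
cat(sprintf("kappa: %.4f\n", metrics$kappa))
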