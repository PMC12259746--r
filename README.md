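# habnet

Graph-based habitat connectivity and fragmentation analysis on categorical
land-cover rasters, in R.

habnet is for landscape ecologists and conservation planners who want to ask:
*how easily can a forest species move between habitat patches across this
landscape, and how did that change between two mapping epochs?* The
motivating use case is hardwood-forest habitat for a medium-sized forest
mustelid (stone-marten-like dispersal of about 5 km) in an Atlantic rural
basin, but every parameter — the resistance table, the habitat class, the
minimum patch area, the dispersal threshold — is configurable.

## What it computes

From a 30 m land-cover raster (six classes: agricultural/herbaceous,
artificial, conifers, hardwoods, eucalyptus, water) and linear
infrastructure, the pipeline builds:

- a **resistance surface**: per-class friction values (hardwoods 1 …
  artificial 1000) with buffered roads (100, 30 m), railways (150, 30 m)
  and highways (1000, 40 m) burned in by a max rule;
- **habitat patches**: 8-connected hardwood components with area ≥ 20 ha;
- **least-cost effective distances** `d_ij` between all patch pairs
  (mean-resistance step costs, √2 diagonals, free movement inside patches)
  and deterministic corridor polylines;
- a **habitat graph** with edges where `d_ij ≤ θ` (default 5000 cost-m) and
  link counts `nl_ij`, carrying

  - IIC `= (1/A²) Σᵢ Σⱼ aᵢaⱼ/(1 + nl_ij)` — topological connectivity in [0,1],
  - PC `= (1/A²) Σᵢ Σⱼ aᵢaⱼ e^(−α d_ij)` — kernel-based connection probability,
  - EC `= √(Σᵢ Σⱼ aᵢaⱼ e^(−α d_ij))` — equivalent connected area (`EC = A√PC`),
  - BC — per-patch betweenness summing `aⱼ^β aₖ^β e^(−α d_jk)` over pairs
    routed through the patch,

  with α calibrated so the kernel is 0.5 at the nominal dispersal distance,
  swept over 1000/3000/5000/7000/9000 m;
- **fragmentation indices**: SPLIT `= A_t²/Σaᵢ²`, effective mesh size
  EM `= Σaᵢ²/A_t`, edge length EL `= ΣEᵢ`, edge density
  ED `= EL/A_t·10⁴`;
- **two-epoch change tables** (percent change for metrics, share-point
  change for cover composition);
- an **occurrence-record analysis**: research-grade filtering, distance of
  each record to the nearest patch or corridor, a seeded 200-point random
  null, and a compact-kernel record heatmap;
- **accuracy assessment** for any predicted/validated pair of categorical
  rasters: confusion matrix, commission/omission, overall accuracy and
  Cohen's kappa.

A seeded synthetic-landscape generator (region-grown class blobs,
extent-crossing infrastructure, habitat-attracted occurrences, epoch
perturbation) makes the whole pipeline runnable and testable with no
external data. I/O is plain text: ESRI ASCII grids for rasters, GeoJSON for
polylines, CSV for tables and records.

## Worked example

```r
library(habnet)

spec <- landscape_spec(n_rows = 60, n_cols = 60, seed = 42,
                       n_occurrences = 50)
lc13 <- generate_landcover(spec)                    # epoch A
lc23 <- perturb_epoch(lc13,                          # epoch B: 10% of
        data.frame(from = "agricultural/herbaceous", # farmland converts
                   to = "hardwoods", fraction = 0.1),# to hardwoods
        seed = 43)

cfg <- run_config(
  epochs = list(
    e2013 = list(landcover = lc13,
                 features = generate_infrastructure(spec),
                 occurrences = generate_occurrences(spec, lc13)),
    e2023 = list(landcover = lc23)),
  min_area = 10 * 900,   # 0.9 ha minimum on this 1.8 km toy extent
  null_n = 200, null_seed = 7)

a <- run_epoch(cfg, "e2013")
b <- run_epoch(cfg, "e2023")
patch_summary(a$patches)
#> $count [1] 3   $min [1] 0.0207   $max [1] 0.2916   $total [1] 0.522  (km²)

cmp <- compare_epochs(a, b)
round(cmp$global_change[, c("distance_m", "iic_a", "pc_a",
                            "iic_change_pct", "pc_change_pct")], 5)
#>   distance_m   iic_a    pc_a iic_change_pct pc_change_pct
#> 1       1000 0.01233 0.01233       42.49471      42.85575
#> 2       3000 0.01233 0.01235       42.49471      59.10205
#> 3       5000 0.01233 0.01242       42.49471      82.92151
#> 4       7000 0.01233 0.01251       42.49471     101.91631
#> 5       9000 0.01233 0.01262       42.49471     115.53777
```

IIC is constant down the sweep (it has no dispersal kernel) while PC grows
with the assumed dispersal distance; converting farmland to hardwoods
raises both, here by 42% (IIC) and 43-116% (PC). Fragmentation moves the
same way (`cmp$patch_change`): SPLIT +5.76%, EM +16.08%, ED −6.32%. The
occurrence records, generated with habitat attraction 0.8, sit a mean
40.53 m from the patch-and-corridor network versus 299.73 m for the
200-point random null — the signature of records clustering on habitat.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic fixtures
and write all tables under `results/`:

```sh
Rscript analysis/01_simulate_landscape.R    # two-epoch fixtures (text geodata)
Rscript analysis/02_accuracy_assessment.R   # confusion matrix + kappa
Rscript analysis/03_connectivity_analysis.R # patches, graph, metrics, change
Rscript analysis/04_occurrence_analysis.R   # record distances vs null, heatmap
```

## Layout

- `R/` — package code: grid/raster model and change arithmetic, accuracy
  assessment, resistance surfaces, patch delineation, cost network, metric
  system, occurrence analysis, synthetic generators, pipeline orchestration
- `tests/testthat/` — unit, property and acceptance tests, including
  brute-force oracles for every search component
- `analysis/` — the numbered workflow drivers
- `vignettes/connectivity-methods.Rmd` — full account of the model,
  conventions, parameter choices and limitations
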