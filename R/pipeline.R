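#' Analysis run configuration
#'
#' Bundles every tunable of a two-epoch connectivity run. Defaults are the
#' standard study conditions: the six-class resistance table with 30/30/40 m
#' infrastructure buffers, hardwood habitat with a 20 ha minimum patch, a
#' 5 km dispersal threshold on effective distance, the
#' 1000/3000/5000/7000/9000 m dispersal-distance sweep with half-life kernel
#' calibration (p_theta = 0.5, beta = 0.5), and a 200-point random null.
#'
#' @param epochs named list; each element is a list with `landcover` (path
#'   or `hab_landcover`), optional `features` (path or `hab_features`) and
#'   optional `occurrences` (path or `hab_occurrences`).
#' @param legend land-cover legend (code -> class name).
#' @param resistance a [resistance_table()].
#' @param habitat_class habitat class name.
#' @param min_area minimum patch area, m^2.
#' @param theta dispersal threshold, cost-m.
#' @param distances dispersal-distance sweep, m.
#' @param p_theta kernel value at the nominal dispersal distance.
#' @param beta area exponent for betweenness centrality.
#' @param exclude_taxa taxa dropped from occurrence records.
#' @param null_n,null_seed random-null size and seed.
#' @param out_dir output directory (NULL = do not write files).
#' @return object of class `hab_config`.
#' @export
run_config <- function(epochs, legend = default_legend(),
                       resistance = resistance_table(),
                       habitat_class = "hardwoods", min_area = 2e5,
                       theta = 5000,
                       distances = c(1000, 3000, 5000, 7000, 9000),
                       p_theta = 0.5, beta = 0.5,
                       exclude_taxa = character(0),
                       null_n = 200, null_seed = 1L, out_dir = NULL) {
  stopifnot(length(distances) >= 1, theta > 0)
  structure(list(epochs = epochs, legend = legend, resistance = resistance,
                 habitat_class = habitat_class, min_area = min_area,
                 theta = theta, distances = distances, p_theta = p_theta,
                 beta = beta, exclude_taxa = exclude_taxa, null_n = null_n,
                 null_seed = null_seed, out_dir = out_dir),
            class = "hab_config")
}

#' Read a run configuration from YAML
#'
#' Structured-text mirror of [run_config()]: top-level keys match the
#' function arguments; `legend` is a code -> class mapping and `resistance`
#' holds `cover`, `features` and `buffers` maps.
#'
#' @param path YAML file path.
#' @return a `hab_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  res <- if (is.null(y$resistance)) resistance_table() else {
    resistance_table(cover = unlist(y$resistance$cover),
                     features = unlist(y$resistance$features),
                     buffers = unlist(y$resistance$buffers))
  }
  legend <- if (is.null(y$legend)) default_legend() else unlist(y$legend)
  args <- y[setdiff(names(y), c("resistance", "legend"))]
  do.call(run_config, c(args, list(resistance = res, legend = legend)))
}

resolve_landcover <- function(x, cfg) {
  if (inherits(x, "hab_landcover")) x else read_landcover(x, cfg$legend)
}
resolve_features <- function(x) {
  if (is.null(x) || inherits(x, "hab_features")) x
  else read_linear_features(x)
}
resolve_occurrences <- function(x) {
  if (is.null(x) || inherits(x, "hab_occurrences")) x
  else read_occurrences(x)
}

#' Run the full connectivity analysis for one epoch
#'
#' Executes the stage sequence resistance surface -> habitat patches ->
#' least-cost network -> habitat graph -> connectivity and fragmentation
#' metrics -> occurrence distance analysis (skipped when the epoch has no
#' occurrence records). Any stage failure is rethrown with the stage name.
#' When `cfg$out_dir` is set, every table is written as CSV under
#' `out_dir/<epoch>/` together with a parameter log.
#'
#' @param cfg a [run_config()].
#' @param epoch name of the epoch entry in `cfg$epochs`.
#' @return list with `cover`, `patches`, `cost_matrix`, `graph`,
#'   `global_metrics`, `fragmentation`, `bc`, `paths`, and (when records are
#'   supplied) `occ_summary` and `occ_null`.
#' @export
run_epoch <- function(cfg, epoch) {
  stopifnot(inherits(cfg, "hab_config"))
  ep <- cfg$epochs[[epoch]]
  if (is.null(ep)) stop("unknown epoch: ", epoch, call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed for epoch ", epoch, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }
  lc <- stage("read_landcover", resolve_landcover(ep$landcover, cfg))
  cover <- stage("tabulate_cover", tabulate_cover(lc))
  rg <- stage("resistance", {
    r <- landcover_resistance(lc, cfg$resistance)
    feats <- resolve_features(ep$features)
    if (!is.null(feats)) r <- burn_linear_features(r, feats, cfg$resistance)
    r
  })
  ps <- stage("patches",
              extract_patches(lc, cfg$habitat_class, cfg$min_area))
  cm <- stage("cost_distance", cost_distance(rg, ps))
  g <- stage("graph", build_graph(ps, cm, cfg$theta))
  sweep <- stage("global_metrics",
                 distance_sweep(ps, cm, g, cfg$distances,
                                p_theta = cfg$p_theta, beta = cfg$beta))
  frag <- if (nrow(ps$patches)) stage("fragmentation",
                                      fragmentation_metrics(ps)) else NULL
  bc_params <- connectivity_params(cfg$theta, p_theta = cfg$p_theta,
                                   beta = cfg$beta, theta = cfg$theta)
  bc <- stage("betweenness", metric_bc(g, bc_params))
  paths <- stage("corridors", edge_paths(rg, ps, g))
  out <- list(epoch = epoch, landcover = lc, cover = cover,
              resistance = rg, patches = ps, cost_matrix = cm, graph = g,
              global_metrics = sweep, fragmentation = frag,
              bc = data.frame(id = ps$patches$id, bc = bc), paths = paths)
  occ <- resolve_occurrences(ep$occurrences)
  if (!is.null(occ) && nrow(ps$patches) > 0) {
    occ <- stage("occurrence_filter", filter_records(occ, cfg$exclude_taxa))
    if (nrow(occ)) {
      out$occ_summary <- stage("occurrence_distance",
                               distance_to_network(occ, ps, paths))
      out$occ_null <- stage("occurrence_null",
                            random_null(lc$grid, cfg$null_n, cfg$null_seed,
                                        ps, paths))
      out$occurrences <- occ
    }
  }
  if (!is.null(cfg$out_dir)) write_epoch_outputs(out, cfg)
  out
}

write_epoch_outputs <- function(out, cfg) {
  dir_ <- file.path(cfg$out_dir, out$epoch)
  dir.create(dir_, recursive = TRUE, showWarnings = FALSE)
  write.csv(out$cover, file.path(dir_, "cover.csv"), row.names = FALSE)
  write_patches(out$patches, file.path(dir_, "patches.csv"))
  write_cost_matrix(out$cost_matrix, file.path(dir_, "cost_matrix.csv"))
  write.csv(out$global_metrics, file.path(dir_, "global_metrics.csv"),
            row.names = FALSE)
  if (!is.null(out$fragmentation)) {
    write.csv(out$fragmentation, file.path(dir_, "patch_metrics.csv"),
              row.names = FALSE)
  }
  write.csv(out$bc, file.path(dir_, "bc.csv"), row.names = FALSE)
  if (!is.null(out$occ_summary)) {
    write.csv(data.frame(n = out$occ_summary$n, mean = out$occ_summary$mean,
                         median = out$occ_summary$median,
                         max = out$occ_summary$max,
                         null_mean = out$occ_null$null_mean,
                         null_n = out$occ_null$null_n,
                         null_seed = out$occ_null$seed),
              file.path(dir_, "occurrence_summary.csv"), row.names = FALSE)
  }
  alpha_nominal <- -log(cfg$p_theta) / cfg$theta
  writeLines(c(
    sprintf("epoch: %s", out$epoch),
    sprintf("habitat_class: %s", cfg$habitat_class),
    sprintf("min_area_m2: %g", cfg$min_area),
    sprintf("theta_cost_m: %g", cfg$theta),
    sprintf("distances_m: %s", paste(cfg$distances, collapse = ",")),
    sprintf("p_theta: %g (alpha at theta = %g per m)", cfg$p_theta,
            alpha_nominal),
    sprintf("beta: %g", cfg$beta),
    sprintf("null_n: %d  null_seed: %d", cfg$null_n, cfg$null_seed),
    "effective_distance: cost-weighted meters, mean-resistance steps,",
    "  sqrt(2) diagonals, zero cost inside patches"
  ), file.path(dir_, "run_log.txt"))
  invisible(dir_)
}

#' Compare two analyzed epochs
#'
#' Builds the three comparison tables of a two-epoch report: cover
#' composition (areas, shares and share-point change), global connectivity
#' metrics by dispersal distance (IIC/PC/EC with percent change), and
#' fragmentation metrics (SPLIT/EM/EL/ED with percent change). Change
#' columns recompute exactly from the two value columns via
#' [percent_change()] / [share_point_change()].
#'
#' @param a,b epoch results from [run_epoch()].
#' @param out_dir optional directory for the comparison CSVs.
#' @return list of data.frames `cover_change`, `global_change`,
#'   `patch_change`.
#' @export
compare_epochs <- function(a, b, out_dir = NULL) {
  if (is.null(a$global_metrics) || is.null(b$global_metrics)) {
    stop("both epochs need global metrics", call. = FALSE)
  }
  cover <- merge(a$cover, b$cover, by = "class", suffixes = c("_a", "_b"),
                 sort = FALSE)
  cover_change <- data.frame(
    class = cover$class,
    area_km2_a = cover$area_km2_a, share_pct_a = cover$share_pct_a,
    area_km2_b = cover$area_km2_b, share_pct_b = cover$share_pct_b,
    change_pp = share_point_change(cover$share_pct_a, cover$share_pct_b))
  ga <- a$global_metrics; gb <- b$global_metrics
  if (!identical(ga$distance_m, gb$distance_m)) {
    stop("epochs were run with different dispersal-distance sweeps",
         call. = FALSE)
  }
  global_change <- data.frame(
    distance_m = ga$distance_m,
    iic_a = ga$iic, pc_a = ga$pc, ec_km2_a = ga$ec_km2,
    iic_b = gb$iic, pc_b = gb$pc, ec_km2_b = gb$ec_km2,
    iic_change_pct = percent_change(ga$iic, gb$iic),
    pc_change_pct = percent_change(ga$pc, gb$pc),
    ec_change_pct = percent_change(ga$ec_km2, gb$ec_km2))
  if (is.null(a$fragmentation) || is.null(b$fragmentation)) {
    stop("fragmentation metrics missing in one epoch", call. = FALSE)
  }
  fa <- a$fragmentation; fb <- b$fragmentation
  va <- c(SPLIT = fa$split, EM_km2 = fa$em_km2, EL_km = fa$el_km,
          ED_km_per_km2 = fa$ed_km_per_km2)
  vb <- c(SPLIT = fb$split, EM_km2 = fb$em_km2, EL_km = fb$el_km,
          ED_km_per_km2 = fb$ed_km_per_km2)
  patch_change <- data.frame(metric = names(va), value_a = unname(va),
                             value_b = unname(vb),
                             change_pct = percent_change(unname(va),
                                                         unname(vb)))
  out <- list(cover_change = cover_change, global_change = global_change,
              patch_change = patch_change)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
  }
  out
}
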