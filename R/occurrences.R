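#' Occurrence records
#'
#' A thin container for citizen-science occurrence records with projected
#' coordinates. Records can be constructed directly or read from a CSV in
#' the common citizen-science export dialect via [read_occurrences()].
#'
#' @param x,y projected coordinates in meters (raster CRS).
#' @param taxon scientific names.
#' @param date observation dates (`Date` or parseable strings).
#' @param quality_grade character vector (e.g. "research", "casual").
#' @param crs_id CRS identifier of the coordinates.
#' @return object of class `hab_occurrences` (a data.frame).
#' @export
occurrence_set <- function(x, y, taxon, date, quality_grade,
                           crs_id = "LOCAL:TM-METERS") {
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  out <- data.frame(x = x, y = y, taxon = as.character(taxon),
                    date = as.Date(date),
                    quality_grade = as.character(quality_grade),
                    stringsAsFactors = FALSE)
  structure(out, crs_id = crs_id,
            class = c("hab_occurrences", "data.frame"))
}

#' Read occurrence records from CSV
#'
#' Accepts the usual citizen-science export columns: `latitude`,
#' `longitude`, `scientific_name` (or `taxon`), `observed_on` (or `date`)
#' and `quality_grade`. Longitude/latitude are projected onto the analysis
#' CRS with a local equirectangular approximation around `origin_lonlat`
#' (adequate at basin scale; sub-meter error over tens of km). Files that
#' already carry projected `x`/`y` columns are taken as-is.
#'
#' @param path CSV path.
#' @param origin_lonlat (lon, lat) mapped to `origin_xy`.
#' @param origin_xy projected coordinates of `origin_lonlat`.
#' @param crs_id CRS identifier of the output coordinates.
#' @return a `hab_occurrences`.
#' @export
read_occurrences <- function(path, origin_lonlat = c(0, 0),
                             origin_xy = c(0, 0),
                             crs_id = "LOCAL:TM-METERS") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  taxon <- if (!is.null(df$scientific_name)) df$scientific_name else df$taxon
  date <- if (!is.null(df$observed_on)) df$observed_on else df$date
  if (!is.null(df$x) && !is.null(df$y)) {
    x <- df$x; y <- df$y
  } else {
    if (is.null(df$longitude) || is.null(df$latitude)) {
      stop("need x/y or longitude/latitude columns", call. = FALSE)
    }
    xy <- project_lonlat(df$longitude, df$latitude, origin_lonlat, origin_xy)
    x <- xy[, 1]; y <- xy[, 2]
  }
  occurrence_set(x, y, taxon, date, df$quality_grade, crs_id = crs_id)
}

# Local equirectangular projection: meters east/north of an origin lon/lat.
project_lonlat <- function(lon, lat, origin_lonlat = c(0, 0),
                           origin_xy = c(0, 0)) {
  R <- 6371008.8
  cbind(x = origin_xy[1] + (lon - origin_lonlat[1]) * pi / 180 * R *
          cos(origin_lonlat[2] * pi / 180),
        y = origin_xy[2] + (lat - origin_lonlat[2]) * pi / 180 * R)
}

#' Filter occurrence records to research grade, excluding listed taxa
#'
#' Keeps records with quality grade "research" and drops taxa on the
#' exclusion list (livestock and non-representative species). Counts per
#' taxon and per year of the retained records are attached as attributes
#' `taxon_counts` and `year_counts`.
#'
#' @param occ a `hab_occurrences`.
#' @param exclude_taxa character vector of taxon names to drop.
#' @return filtered `hab_occurrences` (empty result allowed, with warning).
#' @export
filter_records <- function(occ, exclude_taxa = character(0)) {
  stopifnot(inherits(occ, "hab_occurrences"))
  keep <- occ$quality_grade == "research" & !(occ$taxon %in% exclude_taxa)
  out <- occ[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no records left after filtering")
  attr(out, "crs_id") <- attr(occ, "crs_id")
  attr(out, "taxon_counts") <-
    sort(table(out$taxon), decreasing = TRUE)
  attr(out, "year_counts") <- table(format(out$date, "%Y"))
  class(out) <- c("hab_occurrences", "data.frame")
  out
}

#' Distance from each record to the habitat network
#'
#' Euclidean distance from each point to the nearest element of the union of
#' patch cells (0 for points inside a patch cell) and least-cost-path
#' polylines. All geometries must share the projected CRS.
#'
#' @param occ a `hab_occurrences` (or two-column coordinate matrix).
#' @param ps a `hab_patchset`.
#' @param paths list of `hab_lcp` corridors (optional).
#' @return list of class `hab_distsummary`: `n`, `mean`, `median`, `max`
#'   (meters) and the per-record `distances`.
#' @export
distance_to_network <- function(occ, ps, paths = list()) {
  pts <- if (is.matrix(occ)) occ else cbind(occ$x, occ$y)
  if (nrow(ps$patches) == 0L && length(paths) == 0L) {
    stop("empty habitat network: no patches and no paths", call. = FALSE)
  }
  d <- network_distances(pts, ps, paths)
  structure(list(n = nrow(pts), mean = mean(d), median = median(d),
                 max = max(d), distances = d),
            class = "hab_distsummary")
}

#' @export
print.hab_distsummary <- function(x, ...) {
  cat(sprintf(
    "<hab_distsummary> n = %d, mean %.2f m, median %.2f m, max %.2f m\n",
    x$n, x$mean, x$median, x$max))
  invisible(x)
}

network_distances <- function(pts, ps, paths) {
  n <- nrow(pts)
  d <- rep(Inf, n)
  cs <- ps$grid$cell_size
  patch_cells <- unlist(ps$cells, use.names = FALSE)
  if (length(patch_cells)) {
    ctr <- cell_centers(ps$grid, patch_cells)
    for (k in seq_len(n)) {
      dx <- pmax(abs(pts[k, 1] - ctr[, 1]) - cs / 2, 0)
      dy <- pmax(abs(pts[k, 2] - ctr[, 2]) - cs / 2, 0)
      d[k] <- min(d[k], min(sqrt(dx^2 + dy^2)))
    }
  }
  for (p in paths) {
    xy <- p$coords
    if (nrow(xy) == 1L) {
      d <- pmin(d, sqrt((pts[, 1] - xy[1, 1])^2 + (pts[, 2] - xy[1, 2])^2))
      next
    }
    for (s in seq_len(nrow(xy) - 1L)) {
      d <- pmin(d, point_segment_distance(pts[, 1], pts[, 2],
                                          xy[s, 1], xy[s, 2],
                                          xy[s + 1L, 1], xy[s + 1L, 2]))
    }
  }
  d
}

#' Random-point null for distance to the habitat network
#'
#' Draws `n` points uniformly inside the boundary polygon (rejection
#' sampling, seeded) and applies the same distance operator as the observed
#' records, yielding the expected distance of a spatially random point.
#'
#' @param boundary either a `hab_grid` (its full extent rectangle) or a
#'   closed polygon as a two-column coordinate matrix.
#' @param n number of null points (default 200).
#' @param seed RNG seed; the same seed reproduces the same points.
#' @param ps a `hab_patchset`.
#' @param paths list of `hab_lcp`.
#' @return list of class `hab_null`: `null_mean`, `null_n`, `seed`,
#'   `distances`, `points`.
#' @export
random_null <- function(boundary, n = 200, seed = 1L, ps, paths = list()) {
  stopifnot(n > 0)
  pts <- with_seed(seed, sample_in_boundary(boundary, n))
  d <- network_distances(pts, ps, paths)
  structure(list(null_mean = mean(d), null_n = n, seed = seed,
                 distances = d, points = pts),
            class = "hab_null")
}

sample_in_boundary <- function(boundary, n) {
  if (inherits(boundary, "hab_grid")) {
    x0 <- boundary$origin[1]
    y1 <- boundary$origin[2]
    w <- boundary$n_cols * boundary$cell_size
    h <- boundary$n_rows * boundary$cell_size
    return(cbind(x0 + runif(n) * w, y1 - runif(n) * h))
  }
  poly <- as.matrix(boundary)
  if (nrow(poly) < 3L) stop("degenerate boundary polygon", call. = FALSE)
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  if (diff(xr) == 0 || diff(yr) == 0) {
    stop("degenerate boundary polygon", call. = FALSE)
  }
  out <- matrix(NA_real_, n, 2)
  got <- 0L; tries <- 0L
  while (got < n) {
    m <- (n - got) * 2L + 10L
    cand <- cbind(xr[1] + runif(m) * diff(xr), yr[1] + runif(m) * diff(yr))
    inside <- point_in_polygon(cand[, 1], cand[, 2], poly)
    take <- which(inside)
    if (length(take)) {
      take <- take[seq_len(min(length(take), n - got))]
      out[(got + 1L):(got + length(take)), ] <- cand[take, , drop = FALSE]
      got <- got + length(take)
    }
    tries <- tries + 1L
    if (tries > 1000L) stop("boundary polygon rejection sampling failed",
                            call. = FALSE)
  }
  out
}

# even-odd rule point-in-polygon test, vectorized over points
point_in_polygon <- function(px, py, poly) {
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  inside <- rep(FALSE, length(px))
  nv <- nrow(poly) - 1L
  for (s in seq_len(nv)) {
    x1 <- poly[s, 1]; y1 <- poly[s, 2]
    x2 <- poly[s + 1L, 1]; y2 <- poly[s + 1L, 2]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      flip <- crosses & (px < xint)
      inside[flip] <- !inside[flip]
    }
  }
  inside
}

#' Record-density heatmap
#'
#' Per-cell sum of a compact-support Epanechnikov kernel
#' `0.75 * (1 - (d/r)^2)` centered on each record, zero beyond the influence
#' radius, so "influence of r meters per record" is literal.
#'
#' @param occ a `hab_occurrences` (or coordinate matrix).
#' @param grid the `hab_grid` to rasterize onto.
#' @param radius influence radius in meters (default 5000).
#' @return numeric matrix on `grid` (all zero when no records).
#' @export
record_heatmap <- function(occ, grid, radius = 5000) {
  stopifnot(radius > 0)
  pts <- if (is.matrix(occ)) occ else cbind(occ$x, occ$y)
  heat <- matrix(0, grid$n_rows, grid$n_cols)
  if (nrow(pts) == 0L) return(heat)
  cs <- grid$cell_size
  for (k in seq_len(nrow(pts))) {
    col_lo <- max(1L, floor((pts[k, 1] - radius - grid$origin[1]) / cs) + 1L)
    col_hi <- min(grid$n_cols,
                  ceiling((pts[k, 1] + radius - grid$origin[1]) / cs))
    row_lo <- max(1L, floor((grid$origin[2] - pts[k, 2] - radius) / cs) + 1L)
    row_hi <- min(grid$n_rows,
                  ceiling((grid$origin[2] - pts[k, 2] + radius) / cs))
    if (col_lo > col_hi || row_lo > row_hi) next
    rows <- row_lo:row_hi; cols <- col_lo:col_hi
    cx <- grid$origin[1] + (cols - 0.5) * cs
    cy <- grid$origin[2] - (rows - 0.5) * cs
    u2 <- outer((pts[k, 2] - cy)^2, (pts[k, 1] - cx)^2, `+`) / radius^2
    kern <- 0.75 * pmax(1 - u2, 0)
    heat[rows, cols] <- heat[rows, cols] + kern
  }
  heat
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
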