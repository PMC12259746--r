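#' Resistance-to-movement table
#'
#' Unitless multipliers of traversed distance per land-cover class and per
#' linear-infrastructure category, with buffer widths for rasterizing the
#' infrastructure. Defaults follow the friction values commonly proposed for
#' forest mustelids: permeable native forest (hardwoods 1), intermediate
#' forest and farmland (conifers 10, agricultural/herbaceous and eucalyptus
#' 20), strong barriers (water bodies and ordinary roads 100, railways 150)
#' and near-impermeable artificial surfaces and highways (1000). Roads and
#' railways are rasterized with a 30 m buffer, highways with 40 m.
#'
#' @param cover named numeric vector: class name -> resistance (>= 1).
#' @param features named numeric vector over road/railway/highway.
#' @param buffers named numeric vector of buffer half-widths in meters.
#' @return object of class `hab_resistance_table`.
#' @export
resistance_table <- function(
    cover = c("agricultural/herbaceous" = 20, "artificial" = 1000,
              "conifers" = 10, "hardwoods" = 1, "eucalyptus" = 20,
              "water" = 100),
    features = c(road = 100, railway = 150, highway = 1000),
    buffers = c(road = 30, railway = 30, highway = 40)) {
  stopifnot(all(cover >= 1), all(is.finite(cover)),
            all(features >= 1), all(is.finite(features)),
            all(buffers > 0))
  if (!setequal(names(features), c("road", "railway", "highway")) ||
      !setequal(names(buffers), c("road", "railway", "highway"))) {
    stop("feature categories must be road, railway, highway", call. = FALSE)
  }
  structure(list(cover = cover, features = features, buffers = buffers),
            class = "hab_resistance_table")
}

#' Per-cell resistance from land cover
#'
#' Looks up each cell's class in the resistance table; nodata cells stay NA.
#'
#' @param lc a `hab_landcover`.
#' @param table a [resistance_table()].
#' @return object of class `hab_resistance`: the grid plus a numeric
#'   resistance matrix `r`.
#' @export
landcover_resistance <- function(lc, table = resistance_table()) {
  stopifnot(inherits(lc, "hab_landcover"),
            inherits(table, "hab_resistance_table"))
  classes <- landcover_classes(lc)
  missing_cls <- setdiff(unique(classes[!is.na(classes)]),
                         names(table$cover))
  if (length(missing_cls)) {
    stop("no resistance entry for class(es): ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  r <- matrix(unname(table$cover[classes]),
              nrow = lc$grid$n_rows, ncol = lc$grid$n_cols)
  structure(list(grid = lc$grid, r = r), class = "hab_resistance")
}

#' @export
print.hab_resistance <- function(x, ...) {
  cat(sprintf("<hab_resistance> %d x %d @ %g m, r in [%g, %g]\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size,
              min(x$r, na.rm = TRUE), max(x$r, na.rm = TRUE)))
  invisible(x)
}

#' Linear infrastructure features
#'
#' @param geoms list of coordinate matrices (two columns, x/y meters in the
#'   raster CRS), one polyline per feature.
#' @param category character vector over road/railway/highway, one per
#'   feature.
#' @param crs_id CRS identifier the coordinates are expressed in.
#' @return object of class `hab_features`.
#' @export
linear_features <- function(geoms, category, crs_id = "LOCAL:TM-METERS") {
  stopifnot(length(geoms) == length(category))
  if (length(category) && !all(category %in% c("road", "railway", "highway"))) {
    stop("category must be road, railway or highway", call. = FALSE)
  }
  geoms <- lapply(geoms, function(g) {
    g <- as.matrix(g)
    if (nrow(g) < 2 || ncol(g) != 2) {
      stop("each polyline needs >= 2 points with x/y columns", call. = FALSE)
    }
    unname(g)
  })
  structure(list(geoms = geoms, category = as.character(category),
                 crs_id = crs_id),
            class = "hab_features")
}

#' Read linear features from GeoJSON
#'
#' Accepts a FeatureCollection of LineString/MultiLineString features with a
#' `category` property (road/railway/highway). Coordinates must already be in
#' the projected analysis CRS.
#'
#' @param path GeoJSON file path.
#' @param crs_id CRS identifier to record on the feature set.
#' @return a [linear_features()] object.
#' @export
read_linear_features <- function(path, crs_id = "LOCAL:TM-METERS") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  geoms <- list(); category <- character(0)
  for (f in feats) {
    cat_ <- f$properties$category
    g <- f$geometry
    coord_to_mat <- function(cc) {
      do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
    }
    if (identical(g$type, "LineString")) {
      geoms <- c(geoms, list(coord_to_mat(g$coordinates)))
      category <- c(category, cat_)
    } else if (identical(g$type, "MultiLineString")) {
      for (part in g$coordinates) {
        geoms <- c(geoms, list(coord_to_mat(part)))
        category <- c(category, cat_)
      }
    } else {
      stop("unsupported geometry type: ", g$type, call. = FALSE)
    }
  }
  linear_features(geoms, category, crs_id)
}

#' Write linear features as GeoJSON
#'
#' @param feats a `hab_features`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_linear_features <- function(feats, path) {
  features <- lapply(seq_along(feats$geoms), function(i) {
    g <- feats$geoms[[i]]
    list(type = "Feature",
         properties = list(category = feats$category[i]),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(g)),
                                              function(k) c(g[k, 1], g[k, 2]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Burn buffered linear infrastructure into a resistance surface
#'
#' Each cell whose center lies within the buffer of a feature takes
#' `max(existing resistance, feature resistance)`; overlapping buffers
#' likewise combine by max. The max rule is the conservative barrier
#' interpretation where infrastructure crosses already-resistant cover, and
#' makes the overlay monotone (burning never lowers resistance) and
#' idempotent.
#'
#' @param rg a `hab_resistance`.
#' @param feats a [linear_features()] set in the same CRS.
#' @param table a [resistance_table()] supplying feature resistances and
#'   buffer widths.
#' @return a new `hab_resistance`.
#' @export
burn_linear_features <- function(rg, feats, table = resistance_table()) {
  stopifnot(inherits(rg, "hab_resistance"), inherits(feats, "hab_features"))
  if (!identical(feats$crs_id, rg$grid$crs_id)) {
    stop("feature CRS (", feats$crs_id, ") does not match raster CRS (",
         rg$grid$crs_id, ")", call. = FALSE)
  }
  if (length(feats$geoms) == 0L) return(rg)
  r <- rg$r
  grid <- rg$grid
  for (i in seq_along(feats$geoms)) {
    cat_ <- feats$category[i]
    width <- table$buffers[[cat_]]
    value <- table$features[[cat_]]
    hit <- cells_within_buffer(grid, feats$geoms[[i]], width)
    if (length(hit)) r[hit] <- pmax(r[hit], value, na.rm = FALSE)
  }
  structure(list(grid = grid, r = r), class = "hab_resistance")
}

# Linear indices of cells whose center lies within `width` of the polyline.
# Works segment by segment, restricted to each segment's bounding box plus
# the buffer, so cost stays proportional to feature length.
cells_within_buffer <- function(grid, coords, width) {
  cs <- grid$cell_size
  hits <- integer(0)
  for (s in seq_len(nrow(coords) - 1L)) {
    p1 <- coords[s, ]; p2 <- coords[s + 1L, ]
    xmin <- min(p1[1], p2[1]) - width; xmax <- max(p1[1], p2[1]) + width
    ymin <- min(p1[2], p2[2]) - width; ymax <- max(p1[2], p2[2]) + width
    col_lo <- max(1L, floor((xmin - grid$origin[1]) / cs - 0.5) + 1L)
    col_hi <- min(grid$n_cols, ceiling((xmax - grid$origin[1]) / cs + 0.5))
    row_lo <- max(1L, floor((grid$origin[2] - ymax) / cs - 0.5) + 1L)
    row_hi <- min(grid$n_rows, ceiling((grid$origin[2] - ymin) / cs + 0.5))
    if (col_lo > col_hi || row_lo > row_hi) next
    rows <- row_lo:row_hi; cols <- col_lo:col_hi
    idx <- as.vector(outer(rows, (cols - 1L) * grid$n_rows, `+`))
    ctr <- cell_centers(grid, idx)
    d <- point_segment_distance(ctr[, 1], ctr[, 2], p1[1], p1[2],
                                p2[1], p2[2])
    hits <- c(hits, idx[d <= width])
  }
  unique(hits)
}

# Euclidean distance from points (px, py) to segment (x1,y1)-(x2,y2),
# vectorized over points.
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2)
}

#' Write a resistance surface as an ESRI ASCII grid
#'
#' @param rg a `hab_resistance`.
#' @param path output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_resistance <- function(rg, path) {
  write_ascii_grid(rg$r, rg$grid, path)
  writeLines(rg$grid$crs_id, paste0(path, ".crs"))
  invisible(path)
}
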