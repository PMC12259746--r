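#' Grid geometry for raster layers
#'
#' A `hab_grid` describes the geometry shared by every raster layer in an
#' analysis: dimensions, cell size, top-left origin in a projected CRS, the
#' CRS identifier and the nodata sentinel. All layers derived from one grid
#' (land cover, resistance, heatmaps) share this geometry, so areas and
#' distances are always computed in meters.
#'
#' The raster model is row-major with the origin at the top-left corner,
#' pixel-is-area, and half-open cell boundaries; every area in the package is
#' obtained by cell counting on this model.
#'
#' @param n_rows,n_cols grid dimensions (positive integers).
#' @param cell_size cell edge length in meters (default 30, the nominal
#'   resolution of the land-cover product the pipeline targets).
#' @param origin numeric length-2, (x, y) of the top-left corner in projected
#'   coordinates (meters).
#' @param crs_id CRS identifier string; must denote a projected CRS with
#'   meter units. Geographic (degree) identifiers are rejected.
#' @param nodata sentinel value used on disk for missing cells.
#' @return an object of class `hab_grid`.
#' @export
hab_grid <- function(n_rows, n_cols, cell_size = 30,
                     origin = c(0, n_rows * cell_size),
                     crs_id = "LOCAL:TM-METERS", nodata = -9999L) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0, length(origin) == 2)
  if (!is_projected_crs(crs_id)) {
    stop("grid CRS must be projected with meter units, got geographic CRS: ",
         crs_id, call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = as.numeric(cell_size), origin = as.numeric(origin),
         crs_id = crs_id, nodata = nodata),
    class = "hab_grid"
  )
}

#' @export
print.hab_grid <- function(x, ...) {
  cat(sprintf("<hab_grid> %d x %d cells @ %g m, origin (%g, %g), CRS %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2],
              x$crs_id))
  invisible(x)
}

# Heuristic rejection of geographic CRS identifiers; anything naming degrees,
# WGS84 lon/lat codes or proj longlat strings is refused.
is_projected_crs <- function(crs_id) {
  !grepl("4326|4258|CRS84|longlat|latlong|degree", crs_id, ignore.case = TRUE)
}

#' Coordinates of cell centers
#'
#' @param grid a `hab_grid`.
#' @param cells integer linear indices into the grid's matrices (R
#'   column-major order). Defaults to all cells.
#' @return a two-column matrix of (x, y) centers in meters.
#' @export
cell_centers <- function(grid, cells = seq_len(grid$n_rows * grid$n_cols)) {
  row <- (cells - 1L) %% grid$n_rows + 1L
  col <- (cells - 1L) %/% grid$n_rows + 1L
  cbind(x = grid$origin[1] + (col - 0.5) * grid$cell_size,
        y = grid$origin[2] - (row - 0.5) * grid$cell_size)
}

#' Categorical land-cover layer
#'
#' Binds an integer code matrix to a [hab_grid()] and a legend mapping codes
#' to class names. Every non-NA code must appear in the legend.
#'
#' @param codes integer matrix (`n_rows` x `n_cols`), NA for nodata.
#' @param grid a `hab_grid` matching the matrix dimensions.
#' @param legend named character vector: names are code strings, values are
#'   class names (e.g. `c("1" = "hardwoods")`).
#' @return an object of class `hab_landcover`.
#' @export
hab_landcover <- function(codes, grid, legend) {
  stopifnot(inherits(grid, "hab_grid"), is.matrix(codes))
  if (nrow(codes) != grid$n_rows || ncol(codes) != grid$n_cols) {
    stop("code matrix dimensions do not match grid", call. = FALSE)
  }
  if (anyDuplicated(names(legend)) || anyDuplicated(legend)) {
    stop("legend codes and class names must be unique", call. = FALSE)
  }
  known <- as.integer(names(legend))
  present <- sort(unique(as.vector(codes)))
  bad <- setdiff(present[!is.na(present)], known)
  if (length(bad)) {
    stop("codes not in legend: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(grid = grid, codes = codes, legend = legend),
            class = "hab_landcover")
}

#' @export
print.hab_landcover <- function(x, ...) {
  cat(sprintf("<hab_landcover> %d x %d @ %g m; classes: %s\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size,
              paste(x$legend, collapse = ", ")))
  invisible(x)
}

# Class name of each cell (NA for nodata), as a character matrix-shaped vector.
landcover_classes <- function(lc) {
  unname(lc$legend[match(lc$codes, as.integer(names(lc$legend)))])
}

#' Read a categorical land-cover raster (ESRI ASCII grid)
#'
#' Reads a single-band categorical raster in ESRI ASCII grid format
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header, rows top
#' to bottom). A sidecar file `<path>.crs`, if present, supplies the CRS
#' identifier; geographic CRS identifiers are rejected because all area and
#' distance computations require meter units.
#'
#' @param path path to the `.asc` file.
#' @param legend named character vector mapping code strings to class names.
#' @param crs_id CRS identifier override; defaults to the sidecar file or a
#'   local projected placeholder.
#' @return a [hab_landcover()] object.
#' @export
read_landcover <- function(path, legend, crs_id = NULL) {
  g <- read_ascii_grid(path)
  if (is.null(crs_id)) {
    sidecar <- paste0(path, ".crs")
    crs_id <- if (file.exists(sidecar)) {
      trimws(readLines(sidecar, n = 1L))
    } else "LOCAL:TM-METERS"
  }
  if (!is_projected_crs(crs_id)) {
    stop("raster CRS is geographic (degrees): ", crs_id,
         "; reproject to a meter-based projected CRS first", call. = FALSE)
  }
  grid <- hab_grid(nrow(g$values), ncol(g$values), g$cell_size,
                   origin = g$origin, crs_id = crs_id, nodata = g$nodata)
  codes <- g$values
  storage.mode(codes) <- "integer"
  hab_landcover(codes, grid, legend)
}

#' Write a land-cover layer as an ESRI ASCII grid
#'
#' @param lc a `hab_landcover`.
#' @param path output `.asc` path; a `<path>.crs` sidecar records the CRS id.
#' @return `path`, invisibly.
#' @export
write_landcover <- function(lc, path) {
  write_ascii_grid(lc$codes, lc$grid, path)
  writeLines(lc$grid$crs_id, paste0(path, ".crs"))
  invisible(path)
}

# -- plain-text raster I/O ---------------------------------------------------
# ESRI ASCII grid: the one widely understood plain-text raster interchange
# format. Values are written row-major from the top row down.

read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[key]])) stop("ASCII grid header missing ", key)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid data length does not match header dimensions")
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  list(values = m, cell_size = hdr$cellsize,
       origin = c(xll, yll + hdr$nrows * hdr$cellsize),
       nodata = nodata)
}

write_ascii_grid <- function(values, grid, path) {
  m <- values
  m[is.na(m)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    paste("xllcorner", format(grid$origin[1], scientific = FALSE)),
    paste("yllcorner",
          format(grid$origin[2] - grid$n_rows * grid$cell_size,
                 scientific = FALSE)),
    paste("cellsize", format(grid$cell_size, scientific = FALSE)),
    paste("NODATA_value", grid$nodata)
  ), con)
  write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Tabulate land-cover composition
#'
#' Per-class area and share of the landscape, by cell counting. The landscape
#' area `A` is the total non-nodata area; shares therefore sum to 100.
#'
#' @param lc a `hab_landcover`.
#' @return a data.frame with columns `class`, `cells`, `area_km2`,
#'   `share_pct` (one row per legend class, including classes with zero
#'   cells), with the landscape area in km^2 attached as attribute
#'   `landscape_area_km2`.
#' @export
tabulate_cover <- function(lc) {
  n_valid <- sum(!is.na(lc$codes))
  if (n_valid == 0L) stop("all cells are nodata; nothing to tabulate",
                          call. = FALSE)
  cell_km2 <- lc$grid$cell_size^2 / 1e6
  counts <- vapply(as.integer(names(lc$legend)),
                   function(code) sum(lc$codes == code, na.rm = TRUE),
                   integer(1))
  area <- counts * cell_km2
  A <- n_valid * cell_km2
  out <- data.frame(class = unname(lc$legend), cells = counts,
                    area_km2 = area, share_pct = area / A * 100,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "landscape_area_km2") <- A
  out
}

#' Relative (percent) change between two epoch values
#'
#' `(new - old) / old * 100`. This is the change column of the global-metric
#' and patch-metric comparison tables; it is undefined for `old == 0`.
#' Rounding to two decimals happens at the reporting layer, not here.
#'
#' @param old,new numeric vectors (recycled).
#' @return percent change, unrounded.
#' @export
percent_change <- function(old, new) {
  if (any(old == 0)) stop("percent change undefined for old value 0",
                          call. = FALSE)
  (new - old) / old * 100
}

#' Share-point change between two epoch cover shares
#'
#' `share_new - share_old` in percentage points. This — not [percent_change()]
#' of the areas — is what the cover-composition comparison table's change
#' column reports, so both operations are exposed.
#'
#' @param share_old,share_new shares in percent, each in [0, 100].
#' @return difference in percentage points.
#' @export
share_point_change <- function(share_old, share_new) {
  if (any(share_old < 0 | share_old > 100 | share_new < 0 | share_new > 100)) {
    stop("shares must lie in [0, 100]", call. = FALSE)
  }
  share_new - share_old
}
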