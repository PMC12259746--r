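#' Default land-cover legend
#'
#' Integer codes for the six cover classes the pipeline models.
#' @return named character vector (code -> class name).
#' @export
default_legend <- function() {
  c("1" = "agricultural/herbaceous", "2" = "artificial", "3" = "conifers",
    "4" = "hardwoods", "5" = "eucalyptus", "6" = "water")
}

#' Specification of a synthetic landscape
#'
#' Describes the study conditions a generated landscape emulates: a
#' categorical 30 m land-cover grid with spatially autocorrelated class
#' blobs, linear infrastructure crossing the extent, and occurrence records
#' optionally attracted to habitat. The default class shares reproduce an
#' Atlantic rural basin dominated by farmland with a substantial hardwood
#' fraction (agricultural/herbaceous 64.5%, artificial 3.4%, conifers 5.3%,
#' hardwoods 16.1%, eucalyptus 10.4%, water 0.3%).
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size cell size in meters (default 30).
#' @param shares named percent shares per class, summing to 100.
#' @param blob_count named integer: number of growth nuclei per class
#'   (classes absent from the vector default to 3).
#' @param roads,railways,highways numbers of polylines per category.
#' @param n_occurrences number of occurrence records.
#' @param attraction habitat-attraction weight w in [0, 1]: each record is
#'   placed within 2 cells of a habitat cell with probability w, else
#'   uniformly.
#' @param seed RNG seed; every generator is a pure function of (spec, seed).
#' @return object of class `hab_landscape_spec`.
#' @export
landscape_spec <- function(n_rows = 60, n_cols = 60, cell_size = 30,
                           shares = c("agricultural/herbaceous" = 64.5,
                                      "artificial" = 3.4,
                                      "conifers" = 5.3,
                                      "hardwoods" = 16.1,
                                      "eucalyptus" = 10.4,
                                      "water" = 0.3),
                           blob_count = c(hardwoods = 5),
                           roads = 2, railways = 1, highways = 1,
                           n_occurrences = 50, attraction = 0.8,
                           seed = 1L) {
  if (abs(sum(shares) - 100) > 1e-6) {
    stop("class shares must sum to 100, got ", sum(shares), call. = FALSE)
  }
  stopifnot(all(shares >= 0), attraction >= 0, attraction <= 1,
            roads >= 0, railways >= 0, highways >= 0, n_occurrences >= 0)
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 shares = shares, blob_count = blob_count, roads = roads,
                 railways = railways, highways = highways,
                 n_occurrences = n_occurrences, attraction = attraction,
                 seed = seed),
            class = "hab_landscape_spec")
}

spec_grid <- function(spec) {
  hab_grid(spec$n_rows, spec$n_cols, spec$cell_size)
}

#' Generate a synthetic land-cover raster
#'
#' Seeded multi-class region growing: each class receives nuclei, and cells
#' accrete onto random frontier positions of classes still below their
#' target count (classes chosen with probability proportional to their
#' remaining deficit). A class whose frontier is walled in is reseeded on a
#' free cell, so target counts are always met exactly and realized shares
#' match the spec up to integer rounding of cell counts.
#'
#' @param spec a [landscape_spec()].
#' @return a `hab_landcover` on the spec's grid.
#' @export
generate_landcover <- function(spec) {
  stopifnot(inherits(spec, "hab_landscape_spec"))
  with_seed(spec$seed, generate_landcover_impl(spec))
}

generate_landcover_impl <- function(spec) {
  legend <- default_legend()
  classes <- unname(legend)
  shares <- spec$shares[classes]
  shares[is.na(shares)] <- 0
  nr <- spec$n_rows; nc <- spec$n_cols
  N <- nr * nc
  target <- round(shares / 100 * N)
  target[which.max(target)] <- target[which.max(target)] + N - sum(target)
  K <- length(classes)

  assign_vec <- integer(N)          # 0 = unassigned, else class index
  fbuf <- matrix(0L, N, K)          # per-class frontier stacks
  fp <- integer(K)
  counts <- integer(K)
  push <- function(k, cell) {
    fp[k] <<- fp[k] + 1L
    fbuf[fp[k], k] <<- cell
  }
  nb4 <- function(cell) {
    row <- (cell - 1L) %% nr + 1L
    col <- (cell - 1L) %/% nr + 1L
    out <- integer(0)
    if (row > 1L) out <- c(out, cell - 1L)
    if (row < nr) out <- c(out, cell + 1L)
    if (col > 1L) out <- c(out, cell - nr)
    if (col < nc) out <- c(out, cell + nr)
    out
  }
  # nuclei
  free <- sample.int(N, N)          # random permutation for nucleus draws
  free_ptr <- 1L
  next_free <- function() {
    while (free_ptr <= N && assign_vec[free[free_ptr]] != 0L) {
      free_ptr <<- free_ptr + 1L
    }
    if (free_ptr > N) return(NA_integer_)
    free[free_ptr]
  }
  for (k in seq_len(K)) {
    if (target[k] == 0L) next
    nb <- spec$blob_count[classes[k]]
    nb <- if (is.na(nb)) 3L else as.integer(nb)
    nb <- max(1L, min(nb, target[k]))
    for (b in seq_len(nb)) {
      cell <- next_free()
      if (is.na(cell)) break
      assign_vec[cell] <- k
      counts[k] <- counts[k] + 1L
      for (v in nb4(cell)) if (assign_vec[v] == 0L) push(k, v)
    }
  }
  # accretion
  while (any(counts < target)) {
    deficit <- pmax(target - counts, 0L)
    active <- which(deficit > 0L & fp > 0L)
    if (!length(active)) {
      # reseed every deficient class that ran out of frontier
      for (k in which(deficit > 0L)) {
        cell <- next_free()
        if (is.na(cell)) stop("region growing exhausted free cells")
        assign_vec[cell] <- k
        counts[k] <- counts[k] + 1L
        for (v in nb4(cell)) if (assign_vec[v] == 0L) push(k, v)
      }
      next
    }
    k <- if (length(active) == 1L) active else {
      active[sample.int(length(active), 1L, prob = deficit[active])]
    }
    i <- sample.int(fp[k], 1L)
    cell <- fbuf[i, k]
    fbuf[i, k] <- fbuf[fp[k], k]
    fp[k] <- fp[k] - 1L
    if (assign_vec[cell] != 0L) next
    assign_vec[cell] <- k
    counts[k] <- counts[k] + 1L
    for (v in nb4(cell)) if (assign_vec[v] == 0L) push(k, v)
  }
  codes <- matrix(as.integer(names(legend))[assign_vec], nr, nc)
  hab_landcover(codes, spec_grid(spec), legend)
}

#' Generate synthetic linear infrastructure
#'
#' Random polylines spanning the grid extent (entering on one side, leaving
#' on the opposite one, with jittered interior vertices), labeled
#' road/railway/highway.
#'
#' @param spec a [landscape_spec()].
#' @return a [linear_features()] set (empty when all counts are zero).
#' @export
generate_infrastructure <- function(spec) {
  stopifnot(inherits(spec, "hab_landscape_spec"))
  grid <- spec_grid(spec)
  counts <- c(road = spec$roads, railway = spec$railways,
              highway = spec$highways)
  with_seed(spec$seed + 1L, {
    geoms <- list(); category <- character(0)
    w <- grid$n_cols * grid$cell_size
    h <- grid$n_rows * grid$cell_size
    x0 <- grid$origin[1]; y1 <- grid$origin[2]
    for (cat_ in names(counts)) {
      for (b in seq_len(counts[[cat_]])) {
        if (runif(1) < 0.5) {  # left-right crossing
          ys <- y1 - runif(2) * h
          xs <- c(x0, x0 + w)
        } else {               # top-bottom crossing
          xs <- x0 + runif(2) * w
          ys <- c(y1, y1 - h)
        }
        n_mid <- sample(1:3, 1)
        tmid <- sort(runif(n_mid, 0.2, 0.8))
        mx <- xs[1] + tmid * (xs[2] - xs[1]) + rnorm(n_mid, 0, w * 0.05)
        my <- ys[1] + tmid * (ys[2] - ys[1]) + rnorm(n_mid, 0, h * 0.05)
        geoms <- c(geoms, list(cbind(c(xs[1], mx, xs[2]),
                                     c(ys[1], my, ys[2]))))
        category <- c(category, cat_)
      }
    }
    linear_features(geoms, category, grid$crs_id)
  })
}

#' Generate synthetic occurrence records
#'
#' With probability `attraction` a record is placed uniformly within the
#' 3 x 3 cell block centered on a random habitat cell (hence within two cell
#' widths of habitat); otherwise uniformly over the extent. All records are
#' grade "research"; taxa and dates are drawn from a small plausible pool of
#' forest mammals and the 2013-2023 window.
#'
#' @param spec a [landscape_spec()].
#' @param lc the generated `hab_landcover` (supplies the habitat cells).
#' @param habitat_class class treated as habitat (default "hardwoods").
#' @return a `hab_occurrences`.
#' @export
generate_occurrences <- function(spec, lc, habitat_class = "hardwoods") {
  stopifnot(inherits(spec, "hab_landscape_spec"),
            inherits(lc, "hab_landcover"))
  grid <- lc$grid
  code <- as.integer(names(lc$legend)[lc$legend == habitat_class])
  hab_cells <- which(!is.na(lc$codes) & lc$codes == code)
  n <- spec$n_occurrences
  taxa <- c("Martes martes", "Genetta genetta", "Meles meles",
            "Vulpes vulpes", "Sus scrofa", "Capreolus capreolus")
  with_seed(spec$seed + 2L, {
    w <- grid$n_cols * grid$cell_size
    h <- grid$n_rows * grid$cell_size
    x <- numeric(n); y <- numeric(n)
    for (k in seq_len(n)) {
      if (length(hab_cells) && runif(1) < spec$attraction) {
        cell <- hab_cells[sample.int(length(hab_cells), 1L)]
        row <- (cell - 1L) %% grid$n_rows + 1L
        col <- (cell - 1L) %/% grid$n_rows + 1L
        row <- min(max(row + sample(-1:1, 1), 1L), grid$n_rows)
        col <- min(max(col + sample(-1:1, 1), 1L), grid$n_cols)
        x[k] <- grid$origin[1] + (col - 1L + runif(1)) * grid$cell_size
        y[k] <- grid$origin[2] - (row - 1L + runif(1)) * grid$cell_size
      } else {
        x[k] <- grid$origin[1] + runif(1) * w
        y[k] <- grid$origin[2] - runif(1) * h
      }
    }
    occurrence_set(x, y,
                   taxon = sample(taxa, n, replace = TRUE),
                   date = as.Date("2013-01-01") +
                     sample.int(365L * 11L, n, replace = TRUE),
                   quality_grade = rep("research", n),
                   crs_id = grid$crs_id)
  })
}

#' Perturb a land cover into a second epoch
#'
#' Converts a stated fraction of each source class to a target class,
#' preferring cells on the source/target boundary (8-neighborhood contact)
#' so change is spatially contagious, and falling back to random source
#' cells once the boundary is exhausted. The converted count is
#' `round(fraction * source-class cells)`, so a class's share moves by
#' `fraction` times its share.
#'
#' @param lc a `hab_landcover`.
#' @param rules data.frame with columns `from`, `to` (class names) and
#'   `fraction` in [0, 1], applied in row order.
#' @param seed RNG seed.
#' @return a new `hab_landcover`.
#' @export
perturb_epoch <- function(lc, rules, seed = 1L) {
  stopifnot(inherits(lc, "hab_landcover"),
            all(c("from", "to", "fraction") %in% names(rules)))
  if (any(rules$fraction < 0 | rules$fraction > 1)) {
    stop("conversion fraction must lie in [0, 1]", call. = FALSE)
  }
  codes <- lc$codes
  legend <- lc$legend
  code_of <- function(cls) {
    code <- as.integer(names(legend)[legend == cls])
    if (!length(code)) stop("class '", cls, "' not in legend", call. = FALSE)
    code
  }
  with_seed(seed, {
    for (r in seq_len(nrow(rules))) {
      from <- code_of(rules$from[r]); to <- code_of(rules$to[r])
      src <- which(!is.na(codes) & codes == from)
      n_conv <- round(rules$fraction[r] * length(src))
      if (n_conv == 0L) next
      tgt_mask <- !is.na(codes) & codes == to
      near <- src[vapply(src, function(cell) {
        any(tgt_mask[neighbors8(cell, nrow(codes), ncol(codes))])
      }, logical(1))]
      pick <- if (length(near) >= n_conv) {
        near[sample.int(length(near), n_conv)]
      } else {
        rest <- setdiff(src, near)
        c(near, rest[sample.int(length(rest), n_conv - length(near))])
      }
      codes[pick] <- to
    }
  })
  hab_landcover(codes, lc$grid, legend)
}

neighbors8 <- function(cell, nr, nc) {
  row <- (cell - 1L) %% nr + 1L
  col <- (cell - 1L) %/% nr + 1L
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  r2 <- row + dr; c2 <- col + dc
  ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
  (c2[ok] - 1L) * nr + r2[ok]
}

#' Synthetic landscape with known, isolated habitat blobs
#'
#' Grows each requested habitat blob to an exact cell count on a uniform
#' background, keeping a one-cell halo between blobs so each one is a
#' separate patch under 8-connectivity. This provides exact ground truth
#' (blob count and areas) for patch-extraction tests.
#'
#' @param blob_cells integer vector: exact cell count of each habitat blob.
#' @param n_rows,n_cols,cell_size grid geometry.
#' @param background background class name.
#' @param habitat habitat class name.
#' @param seed RNG seed.
#' @return a `hab_landcover` with attribute `true_areas_m2`.
#' @export
generate_patch_truth <- function(blob_cells, n_rows = 60, n_cols = 60,
                                 cell_size = 30,
                                 background = "agricultural/herbaceous",
                                 habitat = "hardwoods", seed = 1L) {
  legend <- default_legend()
  bg <- as.integer(names(legend)[legend == background])
  hb <- as.integer(names(legend)[legend == habitat])
  nr <- n_rows; nc <- n_cols
  with_seed(seed, {
    for (attempt in 1:50) {
      codes <- matrix(bg, nr, nc)
      blocked <- matrix(FALSE, nr, nc)   # halo of finished blobs
      ok_all <- TRUE
      for (b in seq_along(blob_cells)) {
        placed <- grow_blob(codes, blocked, blob_cells[b], hb, bg, nr, nc)
        if (is.null(placed)) { ok_all <- FALSE; break }
        codes <- placed$codes; blocked <- placed$blocked
      }
      if (ok_all) {
        lc <- hab_landcover(codes, hab_grid(nr, nc, cell_size), legend)
        attr(lc, "true_areas_m2") <- sort(blob_cells * cell_size^2,
                                          decreasing = TRUE)
        return(lc)
      }
    }
    stop("could not place all blobs; grid too small for requested areas",
         call. = FALSE)
  })
}

grow_blob <- function(codes, blocked, size, hb, bg, nr, nc) {
  for (try_ in 1:200) {
    free <- which(codes == bg & !blocked)
    if (!length(free)) return(NULL)
    nucleus <- free[sample.int(length(free), 1L)]
    cells <- nucleus
    frontier <- nucleus
    ok <- TRUE
    rook <- function(cell) {
      row <- (cell - 1L) %% nr + 1L; col <- (cell - 1L) %/% nr + 1L
      out <- integer(0)
      if (row > 1L) out <- c(out, cell - 1L)
      if (row < nr) out <- c(out, cell + 1L)
      if (col > 1L) out <- c(out, cell - nr)
      if (col < nc) out <- c(out, cell + nr)
      out
    }
    while (length(cells) < size) {
      cand <- unique(unlist(lapply(frontier, rook)))
      cand <- cand[codes[cand] == bg & !blocked[cand] & !(cand %in% cells)]
      if (!length(cand)) {  # frontier walled in; fall back to whole blob
        cand <- unique(unlist(lapply(cells, rook)))
        cand <- cand[codes[cand] == bg & !blocked[cand] & !(cand %in% cells)]
      }
      if (!length(cand)) { ok <- FALSE; break }
      take <- cand[sample.int(length(cand),
                              min(length(cand), size - length(cells)))]
      cells <- c(cells, take)
      frontier <- take
    }
    if (!ok) next
    codes[cells] <- hb
    halo <- unique(unlist(lapply(cells, neighbors8, nr = nr, nc = nc)))
    blocked[halo] <- TRUE
    return(list(codes = codes, blocked = blocked))
  }
  NULL
}
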