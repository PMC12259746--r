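#' Least-cost effective distances between habitat patches
#'
#' Effective distance is accumulated cost in "cost-weighted meters" over the
#' 8-connected cell lattice: a step between adjacent cells costs the mean of
#' the two cell resistances times the cell size, times sqrt(2) for diagonal
#' moves (the standard cost-distance convention). Movement inside a patch is
#' free (cost 0 between a patch's own cells), so the patch-to-patch distance
#' is edge-to-edge: the cheapest route between any cell of one patch and any
#' cell of the other. In uniform resistance 1, cost-meters equal geometric
#' meters.
#'
#' @param rg a `hab_resistance`.
#' @param ps a `hab_patchset` on the same grid.
#' @return symmetric numeric matrix of effective distances (cost-m) with
#'   zero diagonal; `Inf` marks unreachable pairs.
#' @export
cost_distance <- function(rg, ps) {
  stopifnot(inherits(rg, "hab_resistance"), inherits(ps, "hab_patchset"))
  check_same_grid(rg$grid, ps$grid)
  n <- nrow(ps$patches)
  d <- matrix(0, n, n)
  if (n <= 1L) {
    dimnames(d) <- list(ps$patches$id, ps$patches$id)
    return(d)
  }
  for (p in seq_len(n)) {
    if (any(is.na(rg$r[ps$cells[[p]]]))) {
      stop("patch ", p, " lies on nodata resistance cells", call. = FALSE)
    }
  }
  lat <- build_lattice_graph(rg, ps$labels)
  reps <- vapply(ps$cells, function(cl) lat$vmap[cl[1]], numeric(1))
  d <- igraph::distances(lat$g, v = reps, to = reps,
                         algorithm = "dijkstra")
  d <- (d + t(d)) / 2  # enforce exact symmetry against float asymmetries
  diag(d) <- 0
  dimnames(d) <- list(ps$patches$id, ps$patches$id)
  d
}

check_same_grid <- function(g1, g2) {
  if (g1$n_rows != g2$n_rows || g1$n_cols != g2$n_cols ||
      g1$cell_size != g2$cell_size || any(g1$origin != g2$origin)) {
    stop("layers are on different grids", call. = FALSE)
  }
  invisible(TRUE)
}

# Weighted lattice graph over non-NA resistance cells. `labels` (optional
# patch-label matrix) zeroes the weight of edges internal to one patch.
# Returns the igraph, the cell index of each vertex, and vmap (cell -> vertex
# id, NA off-lattice).
build_lattice_graph <- function(rg, labels = NULL) {
  nr <- rg$grid$n_rows; nc <- rg$grid$n_cols
  cs <- rg$grid$cell_size
  valid <- which(!is.na(rg$r))
  vmap <- rep(NA_real_, nr * nc)
  vmap[valid] <- seq_along(valid)
  row <- (valid - 1L) %% nr + 1L
  col <- (valid - 1L) %/% nr + 1L
  shifts <- list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
                 c(1L, -1L, sqrt(2)))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (s in shifts) {
    r2 <- row + s[1]; c2 <- col + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    src <- valid[ok]
    has <- !is.na(vmap[nb])
    src <- src[has]; nb <- nb[has]
    wt <- (rg$r[src] + rg$r[nb]) / 2 * cs * s[3]
    if (!is.null(labels)) {
      same <- labels[src] > 0L & labels[src] == labels[nb]
      wt[same] <- 0
    }
    from <- c(from, vmap[src]); to <- c(to, vmap[nb]); w <- c(w, wt)
  }
  g <- igraph::make_graph(rbind(from, to), n = length(valid),
                          directed = FALSE)
  igraph::E(g)$weight <- w
  list(g = g, vids = valid, vmap = vmap)
}

# Neighbors of `cell` on the lattice with step multipliers; used by the
# deterministic corridor reconstruction.
lattice_neighbors <- function(cell, nr, nc) {
  row <- (cell - 1L) %% nr + 1L
  col <- (cell - 1L) %/% nr + 1L
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  mult <- c(sqrt(2), 1, sqrt(2), 1, 1, sqrt(2), 1, sqrt(2))
  r2 <- row + dr; c2 <- col + dc
  ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
  list(cells = (c2[ok] - 1L) * nr + r2[ok], mult = mult[ok])
}

#' Deterministic least-cost path between two patches
#'
#' Returns one optimal corridor polyline. Among all minimum-cost routes the
#' one with the fewest steps is chosen, and remaining ties are broken by
#' smallest cell index at every predecessor choice, so the result is unique
#' and reproducible. The reconstruction works on the optimal-move subgraph
#' (cells v with dist_i(v) + dist_j(v) equal to the patch-pair distance), so
#' it never examines cells off any optimal route.
#'
#' @param rg a `hab_resistance`.
#' @param ps a `hab_patchset`.
#' @param i,j patch ids (rows of `ps$patches`).
#' @return object of class `hab_lcp`: `source`, `target`, `cells`, `coords`
#'   (polyline of cell centers) and `effective_distance` in cost-m.
#' @export
least_cost_path <- function(rg, ps, i, j) {
  stopifnot(inherits(rg, "hab_resistance"), inherits(ps, "hab_patchset"))
  n <- nrow(ps$patches)
  stopifnot(i >= 1, i <= n, j >= 1, j <= n, i != j)
  lat <- build_lattice_graph(rg, ps$labels)
  rep_i <- lat$vmap[ps$cells[[i]][1]]
  rep_j <- lat$vmap[ps$cells[[j]][1]]
  di <- as.numeric(igraph::distances(lat$g, v = rep_i,
                                     algorithm = "dijkstra"))
  dj <- as.numeric(igraph::distances(lat$g, v = rep_j,
                                     algorithm = "dijkstra"))
  dij <- di[rep_j]
  if (!is.finite(dij)) {
    stop("patches ", i, " and ", j, " are disconnected on the resistance ",
         "surface", call. = FALSE)
  }
  tol <- 1e-7 * max(1, dij)
  nr <- rg$grid$n_rows; nc <- rg$grid$n_cols
  # dist vectors indexed by cell
  dist_i <- rep(Inf, nr * nc); dist_i[lat$vids] <- di
  dist_j <- rep(Inf, nr * nc); dist_j[lat$vids] <- dj
  on_opt <- is.finite(dist_i) & is.finite(dist_j) &
    (dist_i + dist_j) <= dij + tol

  cs <- rg$grid$cell_size
  labels <- ps$labels
  step_cost <- function(u, v, mult) {
    if (labels[u] > 0L && labels[u] == labels[v]) return(0)
    (rg$r[u] + rg$r[v]) / 2 * cs * mult
  }
  # min-hop BFS over the optimal-move DAG, smallest-index predecessor wins
  hops <- rep(NA_integer_, nr * nc)
  parent <- rep(NA_integer_, nr * nc)
  frontier <- sort(intersect(which(on_opt), ps$cells[[i]]))
  hops[frontier] <- 0L
  target <- NA_integer_
  level <- 0L
  target_cells <- ps$cells[[j]]
  if (any(frontier %in% target_cells)) target <- min(frontier[frontier %in% target_cells])
  while (is.na(target) && length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      nb <- lattice_neighbors(u, nr, nc)
      for (k in seq_along(nb$cells)) {
        v <- nb$cells[k]
        if (!on_opt[v]) next
        if (abs(dist_i[u] + step_cost(u, v, nb$mult[k]) - dist_i[v]) > tol) next
        if (is.na(hops[v])) {
          hops[v] <- level + 1L
          parent[v] <- u
          nxt <- c(nxt, v)
        } else if (hops[v] == level + 1L && u < parent[v]) {
          parent[v] <- u
        }
      }
    }
    frontier <- sort(unique(nxt))
    level <- level + 1L
    reached <- frontier[frontier %in% target_cells]
    if (length(reached)) target <- min(reached)
  }
  if (is.na(target)) {
    stop("optimal-corridor reconstruction failed (numerical tie tolerance)",
         call. = FALSE)
  }
  path <- target
  while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
  eff <- 0
  if (length(path) > 1) {
    for (k in seq_len(length(path) - 1L)) {
      u <- path[k]; v <- path[k + 1L]
      du <- abs((u - 1L) %% nr - (v - 1L) %% nr)
      dv <- abs((u - 1L) %/% nr - (v - 1L) %/% nr)
      eff <- eff + step_cost(u, v, if (du + dv == 2L) sqrt(2) else 1)
    }
  }
  structure(list(source = i, target = j, cells = path,
                 coords = cell_centers(rg$grid, path),
                 effective_distance = eff),
            class = "hab_lcp")
}

#' @export
print.hab_lcp <- function(x, ...) {
  cat(sprintf("<hab_lcp> patch %d -> %d, %d cells, %.1f cost-m\n",
              x$source, x$target, length(x$cells), x$effective_distance))
  invisible(x)
}

#' All least-cost paths for the edges of a habitat graph
#'
#' @param rg a `hab_resistance`.
#' @param ps a `hab_patchset`.
#' @param g a `hab_graph` (paths are computed for its edges only).
#' @return list of `hab_lcp`, one per graph edge.
#' @export
edge_paths <- function(rg, ps, g) {
  stopifnot(inherits(g, "hab_graph"))
  lapply(seq_len(nrow(g$edges)), function(k) {
    least_cost_path(rg, ps, g$edges$i[k], g$edges$j[k])
  })
}

#' Dispersal-thresholded habitat graph
#'
#' Patches are nodes; pairs with effective distance `d_ij <= theta` are
#' joined by an edge. `nl_ij` is the minimum number of edges between i and j
#' on this graph (0 on the diagonal, `Inf` when disconnected); it feeds the
#' integral index of connectivity.
#'
#' @param ps a `hab_patchset`.
#' @param cm cost matrix from [cost_distance()].
#' @param theta dispersal threshold in cost-m (default 5000, a 5 km maximum
#'   dispersal).
#' @return object of class `hab_graph` with the igraph object, an edge table
#'   (`i`, `j`, `d`), the link-count matrix `nl` and node areas.
#' @export
build_graph <- function(ps, cm, theta = 5000) {
  stopifnot(theta > 0)
  n <- nrow(ps$patches)
  adj <- is.finite(cm) & cm <= theta
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  nl <- igraph::distances(g)  # unweighted -> hop counts
  ut <- which(upper.tri(cm) & adj, arr.ind = TRUE)
  edges <- data.frame(i = ut[, 1], j = ut[, 2],
                      d = cm[ut])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(graph = g, edges = edges, nl = nl, theta = theta,
                 areas = ps$patches$area_m2, n = n),
            class = "hab_graph")
}

#' @export
print.hab_graph <- function(x, ...) {
  cat(sprintf("<hab_graph> %d nodes, %d edges (theta = %g cost-m)\n",
              x$n, nrow(x$edges), x$theta))
  invisible(x)
}

#' Export a cost matrix in long format
#'
#' @param cm cost matrix.
#' @param path output CSV path (columns i, j, d_cost_m).
#' @return `path`, invisibly.
#' @export
write_cost_matrix <- function(cm, path) {
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  out <- data.frame(i = ut[, 1], j = ut[, 2], d_cost_m = cm[ut])
  out <- out[order(out$i, out$j), ]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
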