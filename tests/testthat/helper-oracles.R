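# Independent brute-force oracles for the search-based operations, plus
# small fixture builders. The oracles deliberately avoid igraph and the
# package's own Dijkstra/BFS code paths.

# Land cover from a bare code matrix with the default legend.
make_lc <- function(codes, cell_size = 30) {
  habnet::hab_landcover(codes, habnet::hab_grid(nrow(codes), ncol(codes),
                                                cell_size),
                        habnet::default_legend())
}

# Uniform-resistance surface on an n x m grid.
make_rg <- function(r_matrix, cell_size = 30) {
  structure(list(grid = habnet::hab_grid(nrow(r_matrix), ncol(r_matrix),
                                         cell_size),
                 r = r_matrix),
            class = "hab_resistance")
}

oracle_neighbors8 <- function(cell, nr, nc) {
  row <- (cell - 1L) %% nr + 1L
  col <- (cell - 1L) %/% nr + 1L
  out <- list()
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r2 <- row + dr; c2 <- col + dc
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    out[[length(out) + 1L]] <- c((c2 - 1L) * nr + r2,
                                 if (abs(dr) + abs(dc) == 2) sqrt(2) else 1)
  }
  out
}

# Exhaustive branch-and-bound search over all simple lattice paths between
# two cell sets; step cost mean(resistance) * cell_size * multiplier, zero
# between cells sharing a positive patch label.
oracle_cost_distance <- function(r, cells_i, cells_j, cell_size = 30,
                                 labels = NULL) {
  nr <- nrow(r); nc <- ncol(r)
  best <- Inf
  visited <- rep(FALSE, nr * nc)
  in_j <- rep(FALSE, nr * nc); in_j[cells_j] <- TRUE
  step <- function(u, v, mult) {
    if (!is.null(labels) && labels[u] > 0 && labels[u] == labels[v]) return(0)
    (r[u] + r[v]) / 2 * cell_size * mult
  }
  rec <- function(cell, cost) {
    if (cost > best) return(invisible())
    if (in_j[cell]) { best <<- min(best, cost); return(invisible()) }
    visited[cell] <<- TRUE
    for (nb in oracle_neighbors8(cell, nr, nc)) {
      v <- nb[1]
      if (visited[v] || is.na(r[v])) next
      rec(v, cost + step(cell, v, nb[2]))
    }
    visited[cell] <<- FALSE
  }
  for (c0 in cells_i) {
    visited[] <- FALSE
    visited[setdiff(cells_i, c0)] <- TRUE  # other sources covered separately
    rec(c0, 0)
  }
  best
}

# All simple paths between two nodes of a small weighted graph given as an
# edge data.frame (i, j, d).
oracle_all_paths <- function(edges, n, from, to) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]; d <- edges$d[k]
    adj[[i]] <- rbind(adj[[i]], c(j, d))
    adj[[j]] <- rbind(adj[[j]], c(i, d))
  }
  paths <- list()
  rec <- function(path, cost) {
    u <- path[length(path)]
    if (u == to) {
      paths[[length(paths) + 1L]] <<- list(path = path, cost = cost)
      return(invisible())
    }
    nb <- adj[[u]]
    if (is.null(nb)) return(invisible())
    for (k in seq_len(nrow(nb))) {
      v <- nb[k, 1]
      if (v %in% path) next
      rec(c(path, v), cost + nb[k, 2])
    }
  }
  rec(from, 0)
  paths
}

# The canonical route between two nodes: minimum cost, then fewest hops,
# then lexicographically smallest node sequence read backwards from the
# target (matching the smallest-predecessor tie-break).
oracle_route <- function(edges, n, from, to) {
  paths <- oracle_all_paths(edges, n, from, to)
  if (!length(paths)) return(NULL)
  costs <- vapply(paths, `[[`, numeric(1), "cost")
  tol <- 1e-9 * max(1, min(costs))
  cand <- paths[costs <= min(costs) + tol]
  hops <- vapply(cand, function(p) length(p$path) - 1L, integer(1))
  cand <- cand[hops == min(hops)]
  if (length(cand) > 1L) {
    revseqs <- lapply(cand, function(p) rev(p$path))
    ord <- do.call(order, as.data.frame(do.call(rbind, revseqs)))
    cand <- cand[ord]
  }
  cand[[1]]
}

# Brute-force betweenness: sum kernel weights over interior nodes of the
# canonical route of every ordered pair.
oracle_bc <- function(edges, n, areas, alpha, beta) {
  bc <- numeric(n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) next
    r <- oracle_route(edges, n, j, k)
    if (is.null(r)) next
    w <- areas[j]^beta * areas[k]^beta * exp(-alpha * r$cost)
    interior <- setdiff(r$path, c(j, k))
    bc[interior] <- bc[interior] + w
  }
  bc
}

# Stack-based flood-fill labeling (no igraph, no recursion limits).
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(mask)) {
    if (labels[start] > 0L) next
    nxt <- nxt + 1L
    stack <- start
    labels[start] <- nxt
    while (length(stack)) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (nb in oracle_neighbors8(u, nr, nc)) {
        v <- nb[1]
        diag_ <- nb[2] > 1
        if (connectivity == 4 && diag_) next
        if (mask[v] && labels[v] == 0L) {
          labels[v] <- nxt
          stack <- c(stack, v)
        }
      }
    }
  }
  labels
}

# Random small patch graph for BC oracle tests: returns a hab_graph-shaped
# object (metric_bc only touches n, edges, areas) plus the pieces.
random_patch_graph <- function(n, edge_prob = 0.6) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sel <- runif(nrow(ut)) < edge_prob
  edges <- data.frame(i = ut[sel, 1], j = ut[sel, 2],
                      d = runif(sum(sel), 100, 6000))
  areas <- runif(n, 2e5, 5e6)
  g <- structure(list(graph = NULL, edges = edges, nl = NULL, theta = Inf,
                      areas = areas, n = n),
                 class = "hab_graph")
  list(g = g, edges = edges, areas = areas)
}

# Two-patch fixture: blocks of habitat at given column ranges on a uniform
# background, with everything needed for cost tests.
two_patch_fixture <- function(nr = 5, nc = 12, cols_i = 1:2, cols_j = 11:12,
                              r_bg = 1, cell_size = 30) {
  codes <- matrix(1L, nr, nc)
  codes[, cols_i] <- 4L
  codes[, cols_j] <- 4L
  lc <- make_lc(codes, cell_size)
  ps <- habnet::extract_patches(lc, min_area = 0)
  r <- matrix(r_bg, nr, nc)
  r[, cols_i] <- 1; r[, cols_j] <- 1
  rg <- make_rg(r, cell_size)
  list(lc = lc, ps = ps, rg = rg)
}
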