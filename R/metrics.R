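#' Connectivity parameters
#'
#' The dispersal kernel is `exp(-alpha * d)`. The exponent is calibrated so
#' the kernel equals `p_theta` at the nominal dispersal distance
#' (`alpha = -ln(p_theta) / d`); the default `p_theta = 0.5` is the common
#' median-dispersal convention. `beta` scales the influence of patch area in
#' the betweenness weights (`a^beta`); 0.5 keeps large patches influential
#' without letting area dominate position.
#'
#' @param dispersal_distance nominal dispersal distance in meters.
#' @param p_theta kernel value at `dispersal_distance`, in (0, 1).
#' @param beta area exponent for betweenness centrality (>= 0).
#' @param theta graph threshold in cost-m (default 5000).
#' @return object of class `hab_params` with derived `alpha` (1/m).
#' @export
connectivity_params <- function(dispersal_distance, p_theta = 0.5,
                                beta = 0.5, theta = 5000) {
  stopifnot(dispersal_distance > 0, p_theta > 0, p_theta < 1, beta >= 0,
            theta > 0)
  structure(list(dispersal_distance = dispersal_distance, p_theta = p_theta,
                 alpha = -log(p_theta) / dispersal_distance,
                 beta = beta, theta = theta),
            class = "hab_params")
}

#' Integral index of connectivity (IIC)
#'
#' `IIC = (1/A^2) * sum_ij a_i a_j / (1 + nl_ij)` over all ordered patch
#' pairs including `i = j` (`nl_ii = 0`); disconnected pairs contribute 0.
#' IIC is purely topological: it depends on the thresholded graph's link
#' counts, not on the dispersal kernel, so it is constant across dispersal
#' distances for a fixed graph. It ranges from 0 to 1, reaching 1 only when
#' a single patch fills the landscape.
#'
#' @param g a `hab_graph`.
#' @param A landscape area in m^2.
#' @return IIC, dimensionless.
#' @export
metric_iic <- function(g, A) {
  stopifnot(inherits(g, "hab_graph"), A > 0)
  if (g$n == 0L) return(0)
  a <- g$areas
  W <- outer(a, a) / (1 + g$nl)
  W[!is.finite(g$nl)] <- 0
  sum(W) / A^2
}

#' Probability of connectivity (PC)
#'
#' `PC = (1/A^2) * sum_ij a_i a_j exp(-alpha d_ij)` over ordered pairs
#' including the diagonal (`d_ii = 0`): the probability that two points
#' dropped at random on the landscape fall into patches connected under the
#' dispersal kernel.
#'
#' @param ps a `hab_patchset`.
#' @param cm cost matrix (effective distances, cost-m).
#' @param params a [connectivity_params()].
#' @param A landscape area in m^2 (defaults to `ps$A`).
#' @return PC, dimensionless in [0, 1].
#' @export
metric_pc <- function(ps, cm, params, A = ps$A) {
  stopifnot(inherits(ps, "hab_patchset"), inherits(params, "hab_params"),
            A > 0)
  if (nrow(ps$patches) == 0L) return(0)
  pc_kernel_sum(ps$patches$area_m2, cm, params$alpha) / A^2
}

pc_kernel_sum <- function(a, cm, alpha) {
  K <- exp(-alpha * cm)
  K[!is.finite(cm)] <- 0
  sum(outer(a, a) * K)
}

#' Equivalent connectivity (EC)
#'
#' `EC = sqrt(sum_ij a_i a_j exp(-alpha d_ij))`: the area of the single
#' patch that would provide the same probability of connectivity as the
#' whole patch system. It can never fall below the largest patch area, and
#' satisfies `EC = A * sqrt(PC)` exactly.
#'
#' @inheritParams metric_pc
#' @return EC in m^2.
#' @export
metric_ec <- function(ps, cm, params) {
  stopifnot(inherits(ps, "hab_patchset"), inherits(params, "hab_params"))
  if (nrow(ps$patches) == 0L) return(0)
  sqrt(pc_kernel_sum(ps$patches$area_m2, cm, params$alpha))
}

#' Betweenness centrality of habitat patches
#'
#' `BC_i` sums, over ordered patch pairs (j, k) with `j != k` and both
#' different from i whose selected route on the thresholded graph passes
#' through i, the flux weight `a_j^beta * a_k^beta * exp(-alpha * d_jk)`,
#' where `d_jk` is the route's total effective distance. The route between
#' two patches is the minimum-total-distance path by edge weights `d`; ties
#' are broken by fewer hops and then by smallest predecessor id at every
#' node, which makes the selected route unique.
#'
#' @param g a `hab_graph`.
#' @param params a [connectivity_params()].
#' @return numeric vector of BC values, one per patch.
#' @export
metric_bc <- function(g, params) {
  stopifnot(inherits(g, "hab_graph"), inherits(params, "hab_params"))
  n <- g$n
  bc <- numeric(n)
  if (n < 3L || nrow(g$edges) == 0L) return(bc)
  adj <- edge_adjacency(g)
  aw <- g$areas^params$beta
  for (j in seq_len(n)) {
    tree <- dijkstra_tiebreak(n, adj, j)
    for (k in seq_len(n)) {
      if (k == j || !is.finite(tree$dist[k])) next
      w <- aw[j] * aw[k] * exp(-params$alpha * tree$dist[k])
      v <- tree$parent[k]
      while (!is.na(v) && v != j) {
        bc[v] <- bc[v] + w
        v <- tree$parent[v]
      }
    }
  }
  bc
}

# adjacency list with weights from a hab_graph edge table
edge_adjacency <- function(g) {
  adj <- vector("list", g$n)
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges$i[k]; j <- g$edges$j[k]; d <- g$edges$d[k]
    adj[[i]] <- rbind(adj[[i]], c(j, d))
    adj[[j]] <- rbind(adj[[j]], c(i, d))
  }
  adj
}

# Dijkstra with deterministic tie-breaking: a node's label is the triple
# (distance, hops, parent) and a relaxation wins on smaller distance, then
# fewer hops, then smaller parent id. O(n^2) selection — patch graphs are
# small.
dijkstra_tiebreak <- function(n, adj, source) {
  dist <- rep(Inf, n); hops <- rep(Inf, n); parent <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  dist[source] <- 0; hops[source] <- 0
  tol <- 1e-9
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[order(dist[cand], hops[cand], cand)][1L]
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (k in seq_len(nrow(nb))) {
      v <- nb[k, 1]; nd <- dist[u] + nb[k, 2]
      if (v == source) next
      rel_tol <- tol * max(1, abs(nd))
      if (nd < dist[v] - rel_tol) {
        dist[v] <- nd; hops[v] <- hops[u] + 1; parent[v] <- u
      } else if (abs(nd - dist[v]) <= rel_tol &&
                 (hops[u] + 1 < hops[v] ||
                  (hops[u] + 1 == hops[v] && u < parent[v]))) {
        dist[v] <- min(dist[v], nd)
        hops[v] <- hops[u] + 1; parent[v] <- u
      }
    }
  }
  list(dist = dist, hops = hops, parent = parent)
}

#' Splitting index (SPLIT)
#'
#' `SPLIT = A_t^2 / sum(a_i^2)`: the number of equally sized patches that
#' would produce the same fragmentation. 1 for a single patch, n for n equal
#' patches.
#'
#' @param ps a `hab_patchset`.
#' @return SPLIT, dimensionless >= 1.
#' @export
metric_split <- function(ps) {
  a <- ps$patches$area_m2
  if (!length(a)) stop("SPLIT undefined for an empty patch set",
                       call. = FALSE)
  sum(a)^2 / sum(a^2)
}

#' Effective mesh size (EM)
#'
#' `EM = sum(a_i^2) / A_t`: the expected size of the patch a random habitat
#' point falls into. Satisfies `EM * SPLIT = A_t` exactly.
#'
#' @param ps a `hab_patchset`.
#' @return EM in m^2.
#' @export
metric_em <- function(ps) {
  a <- ps$patches$area_m2
  if (!length(a)) stop("EM undefined for an empty patch set", call. = FALSE)
  sum(a^2) / sum(a)
}

#' Edge length (EL) and edge density (ED)
#'
#' `EL = sum(E_i)` is the total patch edge length in meters; `ED = EL / A_t
#' * 1e4` relates it to the habitat area — with meters and m^2 this yields
#' meters of edge per hectare of habitat. The reporting layer also converts
#' to km and km/km^2.
#'
#' @param ps a `hab_patchset`.
#' @return list with `el_m` and `ed_m_per_ha` (`ed` is an error on an empty
#'   set; `el` is then 0).
#' @export
metric_el_ed <- function(ps) {
  e <- ps$patches$perimeter_m
  if (!length(e)) {
    stop("ED undefined for an empty patch set (EL would be 0)",
         call. = FALSE)
  }
  el <- sum(e)
  list(el_m = el, ed_m_per_ha = el / ps$A_t * 1e4)
}

#' Global metrics across a sweep of dispersal distances
#'
#' Recomputes PC and EC with the kernel recalibrated to each nominal
#' dispersal distance (`alpha = -ln(p_theta)/d`); IIC has no kernel and is
#' reported once per row unchanged, mirroring the layout of a
#' global-metrics-by-distance table. PC and EC are non-decreasing in the
#' dispersal distance under this calibration.
#'
#' @param ps a `hab_patchset`.
#' @param cm cost matrix.
#' @param g a `hab_graph`.
#' @param distances dispersal distances in meters (default 1000, 3000, 5000,
#'   7000, 9000).
#' @param p_theta kernel value at the nominal distance (default 0.5).
#' @param beta area exponent passed through to the parameter set.
#' @param A landscape area in m^2 (defaults to `ps$A`).
#' @return data.frame with columns `distance_m`, `iic`, `pc`, `ec_m2`,
#'   `ec_km2`.
#' @export
distance_sweep <- function(ps, cm, g,
                           distances = c(1000, 3000, 5000, 7000, 9000),
                           p_theta = 0.5, beta = 0.5, A = ps$A) {
  stopifnot(all(distances > 0))
  iic <- metric_iic(g, A)
  rows <- lapply(distances, function(d) {
    pr <- connectivity_params(d, p_theta = p_theta, beta = beta,
                              theta = g$theta)
    pc <- metric_pc(ps, cm, pr, A)
    ec <- metric_ec(ps, cm, pr)
    data.frame(distance_m = d, iic = iic, pc = pc, ec_m2 = ec,
               ec_km2 = ec / 1e6)
  })
  do.call(rbind, rows)
}

#' Fragmentation metrics of a patch set
#'
#' @param ps a `hab_patchset`.
#' @return data.frame with one row: SPLIT, EM (m^2 and km^2), EL (m and km),
#'   ED (m/ha and km/km^2).
#' @export
fragmentation_metrics <- function(ps) {
  el_ed <- metric_el_ed(ps)
  em <- metric_em(ps)
  data.frame(split = metric_split(ps),
             em_m2 = em, em_km2 = em / 1e6,
             el_m = el_ed$el_m, el_km = el_ed$el_m / 1e3,
             ed_m_per_ha = el_ed$ed_m_per_ha,
             ed_km_per_km2 = (el_ed$el_m / 1e3) / (ps$A_t / 1e6))
}
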