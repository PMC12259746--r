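# minimal patch-set stub: the global metrics only read patches$area_m2 and A
make_ps <- function(areas, A) {
  structure(list(patches = data.frame(id = seq_along(areas),
                                      area_m2 = areas),
                 A_t = sum(areas), A = A),
            class = "hab_patchset")
}
make_g <- function(edges, areas, nl, theta = 5000) {
  structure(list(graph = NULL, edges = edges, nl = nl, theta = theta,
                 areas = areas, n = length(areas)),
            class = "hab_graph")
}

test_that("IIC worked examples: single patch, linked pair, unlinked pair", {
  # single patch filling the landscape
  nl1 <- matrix(0, 1, 1)
  expect_equal(metric_iic(make_g(data.frame(), 10, nl1), A = 10), 1)
  # two patches a = 1, A = 10, one edge: (1 + 1 + 0.5 + 0.5) / 100
  nl2 <- rbind(c(0, 1), c(1, 0))
  g2 <- make_g(data.frame(i = 1, j = 2, d = 100), c(1, 1), nl2)
  expect_equal(metric_iic(g2, A = 10), 0.03)
  # disconnected: diagonal terms only
  nl0 <- rbind(c(0, Inf), c(Inf, 0))
  g0 <- make_g(data.frame(), c(1, 1), nl0)
  expect_equal(metric_iic(g0, A = 10), 0.02)
})

test_that("PC and EC worked examples and their algebraic identity", {
  params <- connectivity_params(1000)  # alpha = ln(2)/1000
  # two patches with kernel exactly 0.5: d = 1000
  cm <- rbind(c(0, 1000), c(1000, 0))
  ps <- make_ps(c(1, 1), A = 10)
  ps$A <- 10
  expect_equal(metric_pc(ps, cm, params, A = 10), 0.03)
  # single patch filling the landscape
  ps1 <- make_ps(10, A = 10)
  expect_equal(metric_pc(ps1, matrix(0, 1, 1), params, A = 10), 1)
  expect_equal(metric_ec(ps1, matrix(0, 1, 1), params), 10)
  # far-apart limit: kernel vanishes off-diagonal
  cmfar <- rbind(c(0, Inf), c(Inf, 0))
  ps2 <- make_ps(c(3, 4), A = 100)
  expect_equal(metric_pc(ps2, cmfar, params, A = 100), (9 + 16) / 1e4)
  expect_equal(metric_ec(ps2, cmfar, params), 5)
  # EC = A * sqrt(PC) exactly
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    a <- runif(n, 1, 50)
    d <- matrix(runif(n * n, 100, 9000), n); d <- (d + t(d)) / 2; diag(d) <- 0
    A <- sum(a) * runif(1, 1, 3)
    psr <- make_ps(a, A)
    pc <- metric_pc(psr, d, params, A = A)
    ec <- metric_ec(psr, d, params)
    expect_equal(ec, A * sqrt(pc), tolerance = 1e-12)
    expect_gte(ec, max(a))
    expect_true(pc >= 0 && pc <= 1)
  }
})

test_that("betweenness worked example: only the middle of a chain scores", {
  # 3 collinear patches, unit areas; kernel over the 1-3 route = 0.25
  d13 <- 2000; params <- connectivity_params(1000, beta = 0.5)
  edges <- data.frame(i = c(1, 2), j = c(2, 3), d = c(1000, 1000))
  g <- make_g(edges, areas = c(1, 1, 1), nl = NULL)
  bc <- metric_bc(g, params)
  expect_equal(bc, c(0, 2 * exp(-params$alpha * d13), 0))
  expect_equal(bc[2], 0.5)
  # edgeless graph: all zero
  g0 <- make_g(data.frame(i = integer(0), j = integer(0), d = numeric(0)),
               areas = c(1, 1, 1), nl = NULL)
  expect_equal(metric_bc(g0, params), c(0, 0, 0))
})

test_that("betweenness equals brute-force path accounting on small graphs", {
  set.seed(51)
  params <- connectivity_params(3000, beta = 0.5)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    pg <- random_patch_graph(n)
    bc <- metric_bc(pg$g, params)
    ora <- oracle_bc(pg$edges, n, pg$areas, params$alpha, params$beta)
    expect_equal(bc, ora, tolerance = 1e-9)
  }
})

test_that("fragmentation indices: closed forms and the mesh identity", {
  expect_equal(metric_split(make_ps(7, A = 10)), 1)
  expect_equal(metric_split(make_ps(rep(2, 5), A = 100)), 5)
  expect_equal(metric_split(make_ps(c(3, 1), A = 10)), 1.6)
  expect_equal(metric_em(make_ps(c(3, 1), A = 10)), 2.5)
  expect_equal(metric_em(make_ps(4, A = 10)), 4)
  # EM * SPLIT = A_t exactly
  set.seed(12)
  for (rep in 1:10) {
    ps <- make_ps(runif(sample(1:8, 1), 1e5, 9e6), A = 1e9)
    expect_equal(metric_em(ps) * metric_split(ps), ps$A_t,
                 tolerance = 1e-12)
    expect_gte(metric_split(ps), 1)
  }
  empty <- make_ps(numeric(0), A = 10)
  expect_error(metric_split(empty), "empty")
  expect_error(metric_em(empty), "empty")
})

test_that("edge length and density follow perimeter closed forms", {
  codes <- matrix(1L, 12, 12)
  codes[2:4, 2:4] <- 4L    # 3x3 block
  codes[7:10, 7:10] <- 4L  # 4x4 block
  ps <- extract_patches(make_lc(codes), min_area = 0)
  m <- metric_el_ed(ps)
  expect_equal(m$el_m, (4 * 3 + 4 * 4) * 30)
  expect_equal(m$ed_m_per_ha, m$el_m / ps$A_t * 1e4)
  # single square patch of side s: ED = (4 s / s^2) * 1e4
  codes1 <- matrix(1L, 12, 12); codes1[2:7, 2:7] <- 4L
  ps1 <- extract_patches(make_lc(codes1), min_area = 0)
  s <- 6 * 30
  expect_equal(metric_el_ed(ps1)$ed_m_per_ha, 4 * s / s^2 * 1e4)
})

test_that("distance sweep: IIC constant, PC and EC non-decreasing in distance", {
  lc <- generate_landcover(landscape_spec(n_rows = 40, n_cols = 40,
                                          seed = 19))
  ps <- extract_patches(lc, min_area = 4 * 900)
  cm <- cost_distance(landcover_resistance(lc), ps)
  g <- build_graph(ps, cm, 5000)
  sw <- distance_sweep(ps, cm, g)
  expect_equal(sw$distance_m, c(1000, 3000, 5000, 7000, 9000))
  expect_equal(length(unique(sw$iic)), 1L)
  expect_true(all(diff(sw$pc) >= -1e-12))
  expect_true(all(diff(sw$ec_m2) >= -1e-9))
  expect_true(all(sw$pc >= 0 & sw$pc <= 1))
  expect_true(all(sw$iic >= 0 & sw$iic <= 1))
  expect_equal(sw$ec_m2, ps$A * sqrt(sw$pc), tolerance = 1e-9)
})

test_that("adding an edge or shortening a distance never lowers IIC/PC/EC", {
  set.seed(61)
  params <- connectivity_params(5000)
  n <- 5
  a <- runif(n, 1e5, 3e6)
  d <- matrix(runif(n * n, 3000, 12000), n); d <- (d + t(d)) / 2; diag(d) <- 0
  A <- sum(a) * 2
  ps <- make_ps(a, A)
  pc1 <- metric_pc(ps, d, params, A = A)
  d2 <- d; d2[1, 2] <- d2[2, 1] <- d[1, 2] / 2
  expect_gte(metric_pc(ps, d2, params, A = A), pc1)
  g1 <- build_graph(ps, d, theta = 5000)
  g2 <- build_graph(ps, d2, theta = 5000)
  expect_gte(metric_iic(g2, A), metric_iic(g1, A))
})
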