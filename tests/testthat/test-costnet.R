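test_that("uniform resistance gives geometric distance scaled by r", {
  # two 5x2 patches with 9 background columns between them at resistance 1:
  # the nearest cells (columns 2 and 12) are 10 rook steps apart
  fx <- two_patch_fixture(nr = 5, nc = 13, cols_i = 1:2, cols_j = 12:13,
                          r_bg = 1)
  cm <- cost_distance(fx$rg, fx$ps)
  expect_equal(nrow(cm), 2L)
  expect_equal(cm[1, 2], 10 * 30)
  expect_equal(cm[1, 1], 0)
  expect_equal(cm, t(cm))
  # uniform resistance 20 scales linearly
  fx20 <- two_patch_fixture(nr = 5, nc = 13, cols_i = 1:2, cols_j = 12:13,
                            r_bg = 20)
  fx20$rg$r[, 1:2] <- 20; fx20$rg$r[, 12:13] <- 20
  cm20 <- cost_distance(fx20$rg, fx20$ps)
  expect_equal(cm20[1, 2], 20 * 10 * 30)
})

test_that("a high-resistance wall forces the enumerated optimal detour", {
  # 5x5: patches in the corners of column 1 and 5, wall down the middle
  codes <- matrix(1L, 5, 5)
  codes[1, 1] <- 4L; codes[1, 5] <- 4L
  lc <- make_lc(codes)
  ps <- extract_patches(lc, min_area = 0)
  r <- matrix(1, 5, 5)
  r[1:4, 3] <- 1000  # wall with a gap at the bottom
  rg <- make_rg(r)
  cm <- cost_distance(rg, ps)
  ora <- oracle_cost_distance(r, ps$cells[[1]], ps$cells[[2]],
                              labels = ps$labels)
  expect_equal(cm[1, 2], ora, tolerance = 1e-9)
  lcp <- least_cost_path(rg, ps, 1, 2)
  expect_false(any(r[lcp$cells] == 1000))           # detours around the wall
  expect_equal(lcp$effective_distance, cm[1, 2], tolerance = 1e-9)
})

test_that("lattice distances equal exhaustive enumeration on random small grids", {
  set.seed(31)
  for (rep in 1:60) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    if (nr * nc < 4) next
    r <- matrix(sample(c(1, 10, 20, 100, 1000), nr * nc, replace = TRUE),
                nr, nc)
    cells <- sample(nr * nc, 2)
    labels <- matrix(0L, nr, nc)
    labels[cells[1]] <- 1L; labels[cells[2]] <- 2L
    rg <- make_rg(r)
    ps <- structure(list(patches = data.frame(id = 1:2,
                                              area_m2 = c(900, 900)),
                         cells = list(cells[1], cells[2]), labels = labels,
                         grid = rg$grid, A_t = 1800, A = nr * nc * 900),
                    class = "hab_patchset")
    cm <- cost_distance(rg, ps)
    ora <- oracle_cost_distance(r, cells[1], cells[2], labels = labels)
    expect_equal(cm[1, 2], ora, tolerance = 1e-9)
  }
})

test_that("raising a cell's resistance never shortens any distance", {
  set.seed(33)
  lc <- generate_landcover(landscape_spec(n_rows = 25, n_cols = 25,
                                          seed = 41))
  ps <- extract_patches(lc, min_area = 3 * 900)
  rg <- landcover_resistance(lc)
  cm <- cost_distance(rg, ps)
  for (rep in 1:5) {
    rg2 <- rg
    bump <- sample(which(!is.na(rg$r) & ps$labels == 0L), 20)
    rg2$r[bump] <- rg2$r[bump] * 10
    cm2 <- cost_distance(rg2, ps)
    expect_true(all(cm2 >= cm - 1e-9))
  }
})

test_that("least-cost path is deterministic, consistent and straight when trivial", {
  fx <- two_patch_fixture(nr = 3, nc = 10, cols_i = 1, cols_j = 10, r_bg = 1)
  p1 <- least_cost_path(fx$rg, fx$ps, 1, 2)
  p2 <- least_cost_path(fx$rg, fx$ps, 1, 2)
  expect_identical(p1$cells, p2$cells)
  # straight rook path: all cells in one row
  rows <- (p1$cells - 1) %% 3 + 1
  expect_equal(length(unique(rows)), 1L)
  cm <- cost_distance(fx$rg, fx$ps)
  expect_equal(p1$effective_distance, cm[1, 2], tolerance = 1e-12)
  # endpoints lie in the source/target patches
  expect_true(p1$cells[1] %in% fx$ps$cells[[1]])
  expect_true(p1$cells[length(p1$cells)] %in% fx$ps$cells[[2]])
})

test_that("disconnected pairs are Inf in the matrix and an error for paths", {
  codes <- matrix(1L, 3, 5)
  codes[2, 1] <- 4L; codes[2, 5] <- 4L
  lc <- make_lc(codes)
  ps <- extract_patches(lc, min_area = 0)
  r <- matrix(1, 3, 5); r[, 3] <- NA  # nodata barrier splits the grid
  rg <- make_rg(r)
  cm <- cost_distance(rg, ps)
  expect_true(is.infinite(cm[1, 2]))
  expect_error(least_cost_path(rg, ps, 1, 2), "disconnected")
})

test_that("thresholded graph edges and link counts follow the distances", {
  cm <- rbind(c(0, 4000, 8000),
              c(4000, 0, 4000),
              c(8000, 4000, 0))
  ps <- structure(list(patches = data.frame(id = 1:3,
                                            area_m2 = c(1, 1, 1) * 9e5)),
                  class = "hab_patchset")
  g <- build_graph(ps, cm, theta = 5000)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(g$nl[1, 3], 2)
  expect_equal(g$nl[1, 2], 1)
  expect_equal(diag(g$nl), c(0, 0, 0))
  # all pairs beyond theta: edgeless, nl infinite off-diagonal
  g0 <- build_graph(ps, cm, theta = 1000)
  expect_equal(nrow(g0$edges), 0L)
  expect_true(all(is.infinite(g0$nl[upper.tri(g0$nl)])))
  # complete graph: nl = 1 everywhere off-diagonal
  g1 <- build_graph(ps, cm, theta = 10000)
  expect_true(all(g1$nl[upper.tri(g1$nl)] == 1))
  # edges shrink monotonically as theta decreases
  expect_true(all(g0$edges$d %in% g$edges$d))
})
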