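test_that("record filtering keeps research grade and drops excluded taxa", {
  occ <- occurrence_set(x = c(0, 10, 20, 30), y = c(0, 10, 20, 30),
                        taxon = c("Martes martes", "Ovis aries",
                                  "Martes martes", "Vulpes vulpes"),
                        date = as.Date("2020-06-01") + 0:3,
                        quality_grade = c("research", "research", "casual",
                                          "research"))
  out <- filter_records(occ, exclude_taxa = "Ovis aries")
  expect_equal(nrow(out), 2L)
  expect_false("Ovis aries" %in% out$taxon)
  expect_equal(sum(attr(out, "taxon_counts")), nrow(out))
  expect_warning(filter_records(occ, exclude_taxa = unique(occ$taxon)),
                 "no records")
})

test_that("distance to the network matches analytic point geometry", {
  codes <- matrix(1L, 10, 10)
  codes[3:5, 3:5] <- 4L
  lc <- make_lc(codes)
  ps <- extract_patches(lc, min_area = 0)
  g <- lc$grid
  inside <- cell_centers(g, which(ps$labels == 1L)[1])
  # a point inside a patch cell has distance 0
  d0 <- distance_to_network(rbind(inside), ps)
  expect_equal(d0$distances, 0)
  # a point due east of the patch edge: analytic offset from the cell border
  right_edge_x <- g$origin[1] + 5 * 30  # right face of column 5
  mid_y <- g$origin[2] - 3.5 * 30
  pt <- cbind(right_edge_x + 77, mid_y)
  expect_equal(distance_to_network(pt, ps)$distances, 77)
  # a path polyline contributes point-segment distances
  path <- structure(list(coords = cbind(c(0, 300), c(-600, -600)),
                         cells = 1:2),
                    class = "hab_lcp")
  ps_empty <- suppressWarnings(extract_patches(make_lc(matrix(1L, 4, 4))))
  dpath <- distance_to_network(cbind(150, -300), ps_empty, list(path))
  expect_equal(dpath$distances, 300)
  # summary statistics on a known distance multiset
  ds <- distance_to_network(rbind(inside,
                                  cbind(right_edge_x + 100, mid_y),
                                  cbind(right_edge_x + 200, mid_y)), ps)
  expect_equal(ds$mean, 100)
  expect_equal(ds$median, 100)
  expect_equal(ds$max, 200)
  # empty network errors
  expect_error(distance_to_network(pt, ps_empty), "empty")
})

test_that("distances are invariant under a joint translation", {
  lc <- generate_landcover(landscape_spec(n_rows = 20, n_cols = 20,
                                          seed = 23))
  ps <- extract_patches(lc, min_area = 0)
  pts <- cbind(runif(10, 0, 600), runif(10, -600, 0))
  d1 <- distance_to_network(pts, ps)$distances
  shift <- c(5000, -3000)
  lc2 <- lc
  lc2$grid$origin <- lc$grid$origin + shift
  ps2 <- extract_patches(lc2, min_area = 0)
  d2 <- distance_to_network(sweep(pts, 2, shift, `+`), ps2)$distances
  expect_equal(d2, d1, tolerance = 1e-9)
})

test_that("random null is seeded, reproducible and zero inside habitat", {
  lc <- generate_landcover(landscape_spec(n_rows = 20, n_cols = 20,
                                          seed = 27))
  ps <- extract_patches(lc, min_area = 0)
  n1 <- random_null(lc$grid, n = 40, seed = 99, ps)
  n2 <- random_null(lc$grid, n = 40, seed = 99, ps)
  expect_identical(n1$points, n2$points)
  expect_identical(n1$null_mean, n2$null_mean)
  n3 <- random_null(lc$grid, n = 40, seed = 100, ps)
  expect_false(identical(n1$points, n3$points))
  # boundary entirely inside one habitat patch -> null mean 0
  all_hab <- extract_patches(make_lc(matrix(4L, 10, 10)), min_area = 0)
  n0 <- random_null(all_hab$grid, n = 20, seed = 1, all_hab)
  expect_equal(n0$null_mean, 0)
  # polygon boundary: sampling respects the polygon
  tri <- rbind(c(0, 0), c(600, 0), c(0, -600))
  np <- random_null(tri, n = 30, seed = 7, ps)
  expect_true(all(np$points[, 1] + (-np$points[, 2]) <= 600 + 1e-9))
  expect_error(random_null(rbind(c(0, 0), c(1, 1)), 10, 1, ps),
               "degenerate")
})

test_that("habitat-attracted records sit closer to the network than the null", {
  spec <- landscape_spec(n_rows = 40, n_cols = 40, seed = 55,
                         n_occurrences = 40, attraction = 0.8)
  lc <- generate_landcover(spec)
  ps <- extract_patches(lc, min_area = 4 * 900)
  wins <- 0L
  for (s in 1:20) {
    sp <- spec; sp$seed <- 1000L + s
    occ <- generate_occurrences(sp, lc)
    obs <- distance_to_network(occ, ps)
    null <- random_null(lc$grid, n = 100, seed = 2000L + s, ps)
    wins <- wins + (obs$mean < null$null_mean)
  }
  expect_gte(wins, 19L)
})

test_that("heatmap kernel has compact support and conserves record peaks", {
  grid <- hab_grid(40, 40, 30)
  # single central record: maximal at the record cell, zero beyond radius
  pt <- cell_centers(grid, (20 - 1) * 40 + 20)
  h <- record_heatmap(pt, grid, radius = 300)
  expect_equal(which.max(h), (20 - 1) * 40 + 20)
  ctr <- cell_centers(grid)
  d <- sqrt((ctr[, 1] - pt[1])^2 + (ctr[, 2] - pt[2])^2)
  expect_true(all(h[d > 300] == 0))
  expect_true(all(h[d < 290] > 0))
  # no records: all-zero surface
  h0 <- record_heatmap(matrix(numeric(0), 0, 2), grid)
  expect_true(all(h0 == 0))
  # two far-apart records yield disjoint nonzero disks
  pts <- rbind(cell_centers(grid, 5), cell_centers(grid, 40 * 40 - 4))
  h2 <- record_heatmap(pts, grid, radius = 150)
  comp <- oracle_label(h2 > 0, 8)
  expect_equal(max(comp), 2L)
})

test_that("occurrence CSV reading projects lon/lat locally", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(latitude = c(42.0, 42.01),
                       longitude = c(-8.0, -8.01),
                       scientific_name = c("Martes martes", "Vulpes vulpes"),
                       observed_on = c("2020-05-01", "2021-06-02"),
                       quality_grade = c("research", "research")),
            path, row.names = FALSE)
  occ <- read_occurrences(path, origin_lonlat = c(-8.0, 42.0))
  expect_equal(nrow(occ), 2L)
  expect_equal(occ$x[1], 0)
  expect_equal(occ$y[1], 0)
  # ~1.11 km north per 0.01 degree latitude
  expect_equal(occ$y[2], 1111.95, tolerance = 1e-3)
  expect_lt(occ$x[2], 0)
  unlink(path)
})
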