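test_that("generators are pure functions of spec and seed", {
  spec <- landscape_spec(n_rows = 30, n_cols = 30, seed = 77)
  expect_identical(generate_landcover(spec)$codes,
                   generate_landcover(spec)$codes)
  f1 <- generate_infrastructure(spec)
  f2 <- generate_infrastructure(spec)
  expect_identical(f1$geoms, f2$geoms)
  lc <- generate_landcover(spec)
  o1 <- generate_occurrences(spec, lc)
  o2 <- generate_occurrences(spec, lc)
  expect_identical(o1$x, o2$x)
  spec2 <- spec; spec2$seed <- 78L
  expect_false(identical(generate_landcover(spec2)$codes, lc$codes))
})

test_that("region growing hits target shares within tolerance", {
  spec <- landscape_spec(n_rows = 200, n_cols = 200, seed = 5)
  lc <- generate_landcover(spec)
  tab <- tabulate_cover(lc)
  for (cls in names(spec$shares)) {
    realized <- tab$share_pct[tab$class == cls]
    expect_lt(abs(realized - spec$shares[[cls]]), 2)
  }
  # degenerate single-class spec gives a uniform raster
  uni <- landscape_spec(n_rows = 10, n_cols = 10,
                        shares = c(hardwoods = 100), seed = 2)
  expect_true(all(generate_landcover(uni)$codes == 4L))
  # infeasible shares rejected
  expect_error(landscape_spec(shares = c(hardwoods = 150)), "sum to 100")
})

test_that("generated landscapes satisfy the raster invariants", {
  for (s in 1:5) {
    lc <- generate_landcover(landscape_spec(n_rows = 25, n_cols = 25,
                                            seed = s))
    expect_s3_class(lc, "hab_landcover")
    expect_true(all(lc$codes %in% as.integer(names(lc$legend))))
    expect_true(is_projected_crs(lc$grid$crs_id))
  }
})

test_that("infrastructure polylines span the extent with valid categories", {
  spec <- landscape_spec(n_rows = 30, n_cols = 30, seed = 7, roads = 3,
                         railways = 2, highways = 1)
  feats <- generate_infrastructure(spec)
  expect_equal(length(feats$geoms), 6L)
  expect_equal(sum(feats$category == "road"), 3L)
  ext_x <- c(0, 30 * 30); ext_y <- c(0, 30 * 30)
  for (g in feats$geoms) {
    expect_true(any(g[, 1] >= ext_x[1] & g[, 1] <= ext_x[2] &
                    g[, 2] >= ext_y[1] & g[, 2] <= ext_y[2]))
  }
  none <- landscape_spec(roads = 0, railways = 0, highways = 0)
  expect_equal(length(generate_infrastructure(none)$geoms), 0L)
})

test_that("occurrence attraction places records near habitat", {
  spec <- landscape_spec(n_rows = 40, n_cols = 40, seed = 15,
                         n_occurrences = 60, attraction = 1)
  lc <- generate_landcover(spec)
  occ <- generate_occurrences(spec, lc)
  ps <- extract_patches(lc, min_area = 0)
  d <- distance_to_network(occ, ps)$distances
  expect_true(all(d <= 60))
  expect_true(all(occ$quality_grade == "research"))
  # attraction 0 behaves like the uniform null across seeds
  spec0 <- spec; spec0$attraction <- 0
  means_occ <- means_null <- numeric(20)
  for (s in 1:20) {
    sp <- spec0; sp$seed <- 300L + s
    means_occ[s] <- distance_to_network(generate_occurrences(sp, lc),
                                        ps)$mean
    means_null[s] <- random_null(lc$grid, n = 60, seed = 600L + s,
                                 ps)$null_mean
  }
  expect_lt(abs(mean(means_occ) - mean(means_null)),
            3 * sd(means_null) / sqrt(20) + 3 * sd(means_occ) / sqrt(20))
})

test_that("epoch perturbation converts the stated fraction of source cells", {
  spec <- landscape_spec(n_rows = 60, n_cols = 60, seed = 31)
  lc <- generate_landcover(spec)
  rules <- data.frame(from = "agricultural/herbaceous", to = "hardwoods",
                      fraction = 0.10)
  lc2 <- perturb_epoch(lc, rules, seed = 4)
  t1 <- tabulate_cover(lc); t2 <- tabulate_cover(lc2)
  agri1 <- t1$share_pct[t1$class == "agricultural/herbaceous"]
  hw_gain <- t2$share_pct[t2$class == "hardwoods"] -
    t1$share_pct[t1$class == "hardwoods"]
  expect_lt(abs(hw_gain - 0.10 * agri1), 0.5)
  # fraction 0 is the identity; fixed seed is deterministic
  expect_identical(perturb_epoch(lc, transform(rules, fraction = 0), 4)$codes,
                   lc$codes)
  expect_identical(perturb_epoch(lc, rules, 4)$codes, lc2$codes)
  expect_error(perturb_epoch(lc, transform(rules, fraction = 1.2), 1),
               "fraction")
})

test_that("patch-truth landscapes have exactly the requested blobs", {
  sizes <- c(40L, 25L, 10L, 7L, 30L)
  lc <- generate_patch_truth(sizes, n_rows = 50, n_cols = 50, seed = 3)
  ps <- extract_patches(lc, min_area = 0)
  expect_equal(nrow(ps$patches), length(sizes))
  expect_equal(ps$patches$area_m2, as.numeric(sort(sizes * 900,
                                                   decreasing = TRUE)))
})
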