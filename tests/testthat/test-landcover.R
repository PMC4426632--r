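test_that("reclassify maps fine codes onto the broad legend", {
  set.seed(42)
  fine <- matrix(sample.int(23, 100, replace = TRUE), 10)
  r <- land_raster(fine, setNames(paste0("f", 1:23), 1:23), 25)
  broad_leg <- setNames(c(LETTERS[1:8], "other"), 1:9)
  map <- data.frame(from = 1:23, to = c(rep(1:8, each = 2), rep(9L, 7)))

  # identity mapping leaves the grid untouched
  id <- reclassify(r, data.frame(from = 1:23, to = 1:23),
                   setNames(paste0("f", 1:23), 1:23))
  expect_identical(id$grid, r$grid)

  # many-to-one: output histogram equals summed input histograms
  out <- reclassify(r, map, broad_leg)
  got <- tabulate(out$grid, 9)
  want <- vapply(1:9, function(b) sum(tabulate(fine, 23)[map$from[map$to == b]]), 1)
  expect_equal(got, want)

  # applying an identity map on the broad legend again is idempotent
  out2 <- reclassify(out, data.frame(from = 1:9, to = 1:9), broad_leg)
  expect_identical(out2$grid, out$grid)

  # unmapped code with no default names the offender
  expect_error(reclassify(r, map[-5, ], broad_leg),
               "unmapped codes.*5", class = "pollscape_legend_error")
  # but a declared default absorbs it
  expect_s3_class(reclassify(r, map[-5, ], broad_leg, default_to = 9L), "land_raster")
})

test_that("buffer rings are distance-correct, disjoint and exhaustive", {
  # single-cell site, radius = 1 cell: exactly the 4 rook neighbours
  m <- matrix(FALSE, 11, 11); m[6, 6] <- TRUE
  zs <- build_zones(m, radii = 100, cell_size = 100)
  ring <- which(zs$annuli[[1]])
  expect_setequal(ring, c(11 * 5 + 6 - 1, 11 * 5 + 6 + 1, 11 * 4 + 6, 11 * 6 + 6))
  expect_false(any(zs$annuli[[1]] & m))

  # brute-force distance check on an irregular site
  site <- matrix(FALSE, 15, 15); site[4:6, 4:7] <- TRUE; site[7, 5] <- TRUE
  radii <- c(200, 400)
  zs2 <- build_zones(site, radii, 100)
  idx <- which(!site)
  sr <- which(site, arr.ind = TRUE)
  for (i in idx) {
    r <- (i - 1) %% 15 + 1; c <- (i - 1) %/% 15 + 1
    d <- min(sqrt((sr[, 1] - r)^2 + (sr[, 2] - c)^2)) * 100
    expect_identical(unname(zs2$annuli[[1]][i]), d <= 200)
    expect_identical(unname(zs2$annuli[[2]][i]), d > 200 && d <= 400)
  }
  # rings disjoint; union equals outer disc minus site
  expect_false(any(zs2$annuli[[1]] & zs2$annuli[[2]]))
  disc_mode <- build_zones(site, radii, 100, mode = "disc")
  expect_identical(zs2$annuli[[1]] | zs2$annuli[[2]], disc_mode$annuli[[2]])

  # sub-cell radius yields an empty, flagged ring
  expect_warning(zs3 <- build_zones(m, radii = 50, cell_size = 100),
                 class = "pollscape_empty_zone")
  expect_true(zs3$flags$empty[zs3$flags$zone == "ring_50m"])
})

test_that("percent cover change is exact and conservative", {
  # 10-cell zone, 3 cells flip A -> B
  g1 <- matrix(1L, 2, 5); g2 <- g1; g2[1, 1:3] <- 2L
  r1 <- toy_raster(g1, K = 2); r2 <- toy_raster(g2, K = 2)
  pc <- percent_change(r1, r2)
  expect_equal(pc$delta_pct, c(-30, 30))

  expect_equal(percent_change(r1, r1)$delta_pct, c(0, 0))

  # conservation on random pairs, with and without nodata
  set.seed(7)
  for (i in 1:25) {
    a <- matrix(sample.int(4, 48, TRUE), 6)
    b <- matrix(sample.int(4, 48, TRUE), 6)
    if (i %% 2 == 0) { a[sample(48, 4)] <- NA; b[sample(48, 4)] <- NA }
    zone <- matrix(sample(c(TRUE, FALSE), 48, TRUE, c(0.8, 0.2)), 6)
    if (!any(zone & !is.na(a) & !is.na(b))) next
    pc <- percent_change(toy_raster(a, K = 4), toy_raster(b, K = 4), zone)
    expect_equal(sum(pc$delta_pct), 0, tolerance = 1e-9)
    expect_equal(sum(pc$cover_hist_pct), 100)
  }

  # all-nodata zone refuses
  an <- matrix(NA_integer_, 2, 2)
  an_r <- land_raster(an, c(`1` = "A"), 100)
  expect_error(percent_change(an_r, an_r), class = "pollscape_nodata_error")
})

test_that("suitability weighting multiplies through and the index sums", {
  g1 <- matrix(1L, 2, 5); g2 <- g1; g2[1, 1:3] <- 2L
  pc <- percent_change(toy_raster(g1, K = 2), toy_raster(g2, K = 2))

  # identity weights reproduce the raw table; index 0 by conservation
  w1 <- weight_change(pc, c(A = 1, B = 1))
  expect_equal(w1$table$weighted_delta, pc$delta_pct)
  expect_equal(w1$index, 0)

  # selector weight picks out one class's change
  expect_equal(weight_change(pc, c(A = 1, B = 0))$index, -30)
  # annihilator
  expect_equal(weight_change(pc, c(A = 0, B = 0))$index, 0)
  # hand arithmetic: 0.8 * (-30) + 0.2 * 30 = -18
  expect_equal(weight_change(pc, c(A = 0.8, B = 0.2))$index, -18)

  expect_error(weight_change(pc, c(A = 0.5)), class = "pollscape_config_error")
})

test_that("adjacency tallies match enumeration on canonical grids", {
  expect_equal(adjacency_matrix(toy_raster(matrix(c(1L, 2L), 1)))["A", "B"], 1)
  m22 <- adjacency_matrix(toy_raster(matrix(1L, 2, 2)))
  expect_equal(m22["A", "A"], 4)
  chk <- matrix(rep_len(c(1L, 2L), 9), 3)
  m33 <- adjacency_matrix(toy_raster(chk))
  expect_equal(m33["A", "B"], 12)
  expect_equal(m33["A", "A"] + m33["B", "B"], 0)
  # double-sided like-adjacency convention doubles the diagonal only
  m22d <- adjacency_matrix(toy_raster(matrix(1L, 2, 2)), double_count_like = TRUE)
  expect_equal(m22d["A", "A"], 8)
})

test_that("edge change differences the tallies and conserves totals", {
  r1 <- toy_raster(matrix(c(1L, 1L, 2L), 1), K = 2)
  r2 <- toy_raster(matrix(c(1L, 2L, 2L), 1), K = 2)
  ec <- edge_change(adjacency_matrix(r1), adjacency_matrix(r2))
  expect_equal(ec$delta["A", "A"], -1)
  expect_equal(ec$delta["B", "B"], 1)
  expect_equal(ec$delta["A", "B"], 0)

  ec0 <- edge_change(adjacency_matrix(r1), adjacency_matrix(r1))
  expect_true(all(ec0$delta == 0))

  # fixed geometry: total adjacency count is conserved, so deltas sum to 0
  set.seed(11)
  for (i in 1:25) {
    a <- matrix(sample.int(3, 30, TRUE), 5)
    b <- matrix(sample.int(3, 30, TRUE), 5)
    ec <- edge_change(adjacency_matrix(toy_raster(a, K = 3)),
                      adjacency_matrix(toy_raster(b, K = 3)))
    ut <- upper.tri(ec$delta, diag = TRUE)
    expect_equal(sum(ec$delta[ut]), 0)
  }

  bad <- adjacency_matrix(toy_raster(matrix(1L, 2, 2), K = 3))
  dimnames(bad) <- list(c("X", "Y", "Z"), c("X", "Y", "Z"))
  expect_error(edge_change(adjacency_matrix(r1), bad),
               class = "pollscape_legend_error")
})

test_that("collinearity screen flags exact dependence and holds its size", {
  set.seed(3)
  x <- rnorm(12)
  scr <- screen_collinearity(data.frame(a = x, b = x, c = -x + 0.001 * rnorm(12)))
  rep_ab <- scr$report[scr$report$var1 == "a" & scr$report$var2 == "b", ]
  expect_equal(rep_ab$r, 1)
  expect_true(rep_ab$forbidden)
  rep_ac <- scr$report[scr$report$var1 == "a" & scr$report$var2 == "c", ]
  expect_lt(rep_ac$r, -0.99)
  expect_true(rep_ac$forbidden)

  expect_warning(scr2 <- screen_collinearity(data.frame(a = x, z = rep(1, 12))),
                 class = "pollscape_zero_variance")
  expect_identical(scr2$dropped, "z")

  # type-I error of the flag is ~alpha for independent predictors
  set.seed(17)
  flags <- replicate(1000, {
    d <- data.frame(p = rnorm(20), q = rnorm(20))
    nrow(screen_collinearity(d)$forbidden) > 0
  })
  expect_gt(mean(flags), 0.03)
  expect_lt(mean(flags), 0.08)
})

test_that("ascii grid round-trips rasters including nodata", {
  set.seed(5)
  g <- matrix(sample.int(3, 24, TRUE), 4); g[2, 3] <- NA
  r <- toy_raster(g, K = 3, cell_size = 50)
  path <- file.path(withr::local_tempdir(), "test.asc")
  write_ascii_grid(r, path)
  r2 <- read_ascii_grid(path)
  expect_identical(r2$grid, r$grid)
  expect_identical(r2$legend, r$legend)
  expect_equal(r2$cell_size, 50)
})
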