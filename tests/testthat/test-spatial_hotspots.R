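test_that("band weights are binary, boundary-inclusive and report isolates", {
  pts <- rbind(c(0, 0), c(10, 0), c(100, 100))
  w5 <- build_weights(pts, 5)
  expect_true(all(w5$w == diag(0, 3) | w5$w == 0))
  expect_setequal(w5$isolates, 1:3)
  w10 <- build_weights(pts, 10)
  expect_equal(w10$w[1, 2], 1)  # exactly at the band: inclusive
  expect_equal(w10$w[2, 1], 1)
  expect_equal(w10$isolates, 3L)
  expect_true(isSymmetric(w10$w))
  ws <- build_weights(pts, 10, include_self = TRUE)
  expect_equal(unname(diag(ws$w)), rep(1, 3))
  expect_error(build_weights(pts, 0), "positive")
  expect_error(build_weights(pts[1, , drop = FALSE], 5), "2 points")
})

test_that("Moran's I equals -1 on the rook checkerboard and matches brute force", {
  coords <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  w <- build_weights(coords, 1)
  m <- global_morans_i(c(1, -1, -1, 1), w)
  expect_equal(m$I, -1)
  expect_equal(m$expected, -1 / 3)
  # brute-force double-sum oracle on random fields
  set.seed(61)
  for (r in 1:10) {
    xy <- matrix(stats::runif(30, 0, 100), 15, 2)
    v <- stats::rnorm(15)
    ww <- build_weights(xy, 45)
    expect_equal(global_morans_i(v, ww)$I, moran_brute(v, ww$w),
                 tolerance = 1e-12)
  }
  expect_error(global_morans_i(rep(1, 4), w), "constant field")
})

test_that("the permutation mean of I matches the closed-form null expectation", {
  set.seed(62)
  xy <- matrix(stats::runif(20, 0, 100), 10, 2)
  w <- build_weights(xy, 50)
  m <- global_morans_i(stats::rnorm(10), w, permutations = 20000)
  mc_se <- stats::sd(m$sims) / sqrt(length(m$sims))
  expect_lt(abs(mean(m$sims) - (-1 / 9)), 4 * mc_se)
})

test_that("shuffled fields rarely look autocorrelated", {
  set.seed(63)
  xy <- matrix(stats::runif(120, 0, 100), 60, 2)
  v <- stats::rnorm(60, 100, 15)
  w <- build_weights(xy, 25)
  ps <- replicate(100, global_morans_i(sample(v), w)$p)
  expect_gte(mean(ps > 0.1), 0.80)
  expect_gte(mean(ps > 0.01), 0.95)
})

test_that("Moran's I stays within [-1, 1] on band weights across random fields", {
  set.seed(64)
  for (r in 1:15) {
    n <- sample(10:40, 1)
    xy <- matrix(stats::runif(2 * n, 0, 100), n, 2)
    w <- build_weights(xy, stats::runif(1, 30, 70))
    if (length(w$isolates) == n) next
    v <- stats::rnorm(n)
    I <- global_morans_i(v, w)$I
    expect_gte(I, -1 - 1e-9)
    expect_lte(I, 1 + 1e-9)
  }
})

test_that("band selection finds cluster-scale bands and rejects white noise", {
  set.seed(65)
  n <- 300
  xy <- cbind(stats::runif(n, 0, 150), stats::runif(n, 0, 150))
  centres <- rbind(c(40, 40), c(110, 100))
  v <- stats::rnorm(n, 100, 5)
  for (k in 1:2) {
    d <- sqrt((xy[, 1] - centres[k, 1])^2 + (xy[, 2] - centres[k, 2])^2)
    v[d <= 30] <- v[d <= 30] + 25
  }
  sel <- choose_distance_band(v, xy, candidates = seq(10, 100, 10))
  expect_true(sel$detected)
  expect_gte(sel$band, 20)
  expect_lte(sel$band, 60)
  # white noise: no candidate reaches the 99% criterion
  noise_sel <- choose_distance_band(stats::rnorm(n, 100, 5), xy,
                                    candidates = seq(20, 100, 20))
  expect_false(noise_sel$detected)
  expect_true(is.na(noise_sel$band))
  expect_error(choose_distance_band(v, xy, candidates = 30), "2 candidate")
})

test_that("Gi* matches brute-force evaluation and is location-invariant", {
  # 3x3 grid with a central spike: corners are the coldest cells
  g <- as.matrix(expand.grid(x = 0:2, y = 0:2))
  vals <- ifelse(g[, 1] == 1 & g[, 2] == 1, 10, 0)
  w <- build_weights(g, 1, include_self = TRUE)
  gi <- getis_ord_gi_star(vals, w)
  for (i in seq_along(vals))
    expect_equal(gi$gi_z[i], gi_star_brute(vals, w$w, i), tolerance = 1e-12)
  corners <- which(g[, 1] != 1 & g[, 2] != 1)
  expect_equal(which(gi$gi_z == min(gi$gi_z)), corners)
  expect_gt(gi$gi_z[5], 0)
  # adding a constant leaves every z unchanged
  gi_shift <- getis_ord_gi_star(vals + 100, w)
  expect_equal(gi_shift$gi_z, gi$gi_z, tolerance = 1e-9)
  expect_error(getis_ord_gi_star(vals, build_weights(g, 1)), "include_self")
  expect_error(getis_ord_gi_star(rep(3, 9), w), "constant field")
})

test_that("closed-form Gi* z agrees with a permutation oracle on 25-point fields", {
  set.seed(66)
  dz <- numeric(20)
  for (r in 1:20) {
    xy <- matrix(stats::runif(50, 0, 100), 25, 2)
    v <- stats::rnorm(25, 100, 10)
    w <- build_weights(xy, 40, include_self = TRUE)
    gi <- getis_ord_gi_star(v, w)
    i <- sample(which(!gi$isolate), 1)
    sims <- replicate(999, sum(w$w[i, ] * sample(v)))
    z_perm <- (sum(w$w[i, ] * v) - mean(sims)) / stats::sd(sims)
    dz[r] <- abs(gi$gi_z[i] - z_perm)
  }
  expect_lt(mean(dz), 0.15)
})

test_that("cluster classification applies the two-sided normal thresholds", {
  z <- c(0, 2.60, -1.70, 1.645, -2.576, 2.575, -1.644, NA)
  cl <- classify_clusters(z)
  expect_equal(as.character(cl),
               c("mean", "very_high", "low", "high", "very_low", "high",
                 "mean", "mean"))
  # exhaustive and disjoint over a random vector
  zz <- stats::rnorm(200, 0, 2)
  expect_equal(sum(table(classify_clusters(zz))), 200)
})

test_that("hotspot GeoJSON round-trips with one feature per plot", {
  res <- data.frame(plot_id = c("a", "b", "c"),
                    lvr = c(100, 120, 90),
                    gi_z = c(0.5, 2.8, -1.9),
                    p_value = c(0.6, 0.005, 0.06),
                    category = classify_clusters(c(0.5, 2.8, -1.9)))
  coords <- data.frame(plot_id = c("a", "b", "c"), x = 1:3, y = 4:6)
  path <- file.path(tempdir(), "hs_test.geojson")
  write_hotspot_map(res, coords, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(doc$type, "FeatureCollection")
  expect_length(doc$features, 3)
  f2 <- doc$features[[2]]
  expect_equal(f2$properties$plot_id, "b")
  expect_equal(f2$properties$category, "very_high")
  expect_equal(f2$geometry$coordinates[[1]], 2)
  pal <- utils::read.csv(sub("\\.geojson$", "_palette.csv", path))
  expect_equal(nrow(pal), 5)
  bad <- coords
  bad$plot_id[1] <- "zzz"
  expect_error(write_hotspot_map(res, bad, path), "keys")
  unlink(c(path, sub("\\.geojson$", "_palette.csv", path)))
})
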