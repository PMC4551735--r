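test_that("relative prices divide by the reference class", {
  pt <- price_table("x", c(FAS = 90, "1C" = 60, "2C" = 30, "3C" = 15))
  expect_equal(compute_relative_prices(pt),
               c(FAS = 1.5, "1C" = 1.0, "2C" = 0.5, "3C" = 0.25))
  # equal prices give all-unit ratios
  eq <- price_table("x", c(FAS = 50, "1C" = 50, "2C" = 50, "3C" = 50))
  expect_true(all(compute_relative_prices(eq) == 1))
  # the 2012 yellow-birch relative price structure
  yb <- compute_relative_prices(default_price_table("yellow_birch"))
  expect_equal(unname(yb[c("FAS", "1C", "2C", "3C")]),
               c(1.81, 1.00, 0.70, 0.25))
  expect_error(price_table("x", c(FAS = 90, "2C" = 30), reference = "1C"),
               "reference")
})

test_that("relative price of the reference class is exactly 1 for any table", {
  set.seed(4)
  for (r in 1:25) {
    p <- stats::runif(4, 10, 400)
    names(p) <- c("FAS", "1C", "2C", "3C")
    ref <- sample(names(p), 1)
    expect_identical(compute_relative_prices(price_table("x", p, ref))[[ref]], 1)
  }
})

test_that("quality index from yields is the yield-weighted relative price", {
  ratios <- c(FAS = 1.81, "1C" = 1.00, "2C" = 0.70, "3C" = 0.25)
  expect_equal(qi_from_yields(c("1C" = 1), ratios), 1.0)
  expect_equal(qi_from_yields(
    c(FAS = 0.4, "1C" = 0.4, "2C" = 0.2, "3C" = 0), ratios), 1.264)
  expect_equal(qi_from_yields(
    c(FAS = 0, "1C" = 0, "2C" = 0, "3C" = 0), ratios), 0)
  expect_error(qi_from_yields(c(FAS = -0.1), ratios), "negative")
})

test_that("QI prediction includes a grade term only when its volume is present", {
  expect_equal(predict_qi(0.5, 0, 0, 0, 0.5), 0.64 + 1.09 * 0.25 / 0.5)
  expect_equal(predict_qi(0, 0, 0.2, 0, 0.4), 0.599)
  zero <- qi_params(0, 0, 0, 0, 0)
  expect_equal(predict_qi(0.1, 0.2, 0, 0, 0.5, zero), 0)
  expect_error(predict_qi(0, 0, 0, 0, 1), "no graded volume")
  expect_error(predict_qi(0.5, 0, 0, 0, 0), "positive")
  # vectorised over trees
  expect_equal(predict_qi(c(0.5, 0), c(0, 0), c(0, 0.2), c(0, 0),
                          c(0.5, 0.4)),
               c(1.185, 0.599))
})

test_that("sawn-wood yield is linear in gross volume and clamped at zero", {
  expect_equal(predict_vsw(1.0), 0.57)
  expect_equal(predict_vsw(0.3, vsw_params(0, 1)), 0.3)
  expect_equal(predict_vsw(0.001), 0)  # gamma0 < 0 region
  expect_error(predict_vsw(0), "positive")
  # non-decreasing in vg when the slope is non-negative
  vg <- sort(stats::runif(50, 0.01, 3))
  expect_true(all(diff(predict_vsw(vg)) >= 0))
})

test_that("lumber value chain multiplies and divides as defined", {
  expect_equal(compute_lv(1.185, 100, 0.57), 67.545)
  expect_equal(compute_lv(0, 100, 0.57), 0)
  expect_equal(compute_lv(1.185, 200, 0.57), 2 * compute_lv(1.185, 100, 0.57))
  expect_error(compute_lv(-1, 100, 0.5), "non-negative")
  expect_equal(compute_lvr(67.545, 0.6), 112.575)
  expect_equal(compute_lvr(0, 2), 0)
  expect_equal(compute_lvr(42, 1), 42)
  expect_error(compute_lvr(10, 0), "positive")
})

test_that("Vsw fit recovers a noiseless line exactly and is OLS with SEs", {
  pairs <- data.frame(vg = c(0.1, 0.5, 1.0), vsw = c(0.048, 0.28, 0.57))
  f <- suppressWarnings(fit_vsw_model(pairs))
  expect_equal(f$params$gamma0, -0.01, tolerance = 1e-10)
  expect_equal(f$params$gamma1, 0.58, tolerance = 1e-10)
  expect_error(fit_vsw_model(data.frame(vg = c(1, 1, 1), vsw = 1:3)),
               "equal")
  # at n = 500 and sd 0.02, estimates land within 3 SE of truth
  spec <- sawing_study_spec(n_logs = 500, vsw_noise_sd = 0.02, seed = 9)
  f2 <- fit_vsw_model(gen_sawing_study(spec))
  expect_lt(abs(f2$params$gamma0 - (-0.01)) / f2$se[1], 3)
  expect_lt(abs(f2$params$gamma1 - 0.58) / f2$se[2], 3)
})

test_that("QI fit recovers noiseless parameters and matches the normal-equations oracle", {
  spec <- sawing_study_spec(n_logs = 40, qi_noise_sd = 0, vsw_noise_sd = 0,
                            seed = 5)
  saw <- gen_sawing_study(spec)
  f <- suppressWarnings(fit_qi_model(saw))
  expect_equal(unlist(f$params),
               c(beta0 = 0.64, beta1 = 1.09, beta2 = 0.60,
                 beta3 = 0.49, beta4 = 0.48),
               tolerance = 1e-8)
  # brute-force normal equations on a small noisy instance
  small <- gen_sawing_study(sawing_study_spec(n_logs = 18, seed = 6))
  fs <- fit_qi_model(small)
  oracle <- qi_normal_equations(small)
  expect_equal(unname(unlist(fs$params)[c("beta0", "beta2", "beta3", "beta4",
                                          "beta1")]),
               unname(oracle), tolerance = 1e-8)
})

test_that("QI fit fails with named parameters when every grade is always present", {
  set.seed(7)
  n <- 20
  vg <- stats::runif(n, 1, 2)
  vf <- matrix(stats::runif(4 * n, 0.05, 0.2), n, 4)
  obs <- data.frame(vf1 = vf[, 1], vf2 = vf[, 2], vf3 = vf[, 3],
                    vf4 = vf[, 4], vg = vg,
                    qi = predict_qi(vf[, 1], vf[, 2], vf[, 3], vf[, 4], vg))
  expect_error(fit_qi_model(obs), "unidentifiable")
})

test_that("tree scoring chains the models and preserves input order", {
  trees <- data.frame(vf1 = c(0.5, 0), vf2 = 0, vf3 = c(0, 0.2), vf4 = 0,
                      vg = c(0.5, 0.4), roundwood_m3 = c(0.6, 0.5))
  pt <- price_table("yellow_birch",
                    c(FAS = 181, "1C" = 100, "2C" = 70, "3C" = 25))
  s <- score_trees(trees, prices = pt)
  # hand chain at vg = 0.5: QI 1.185, Vsw 0.28, LV 33.18, LVR 33.18/0.6
  expect_equal(s$qi, c(1.185, 0.599))
  expect_equal(s$vsw[1], 0.28)
  expect_equal(s$lv[1], 33.18)
  expect_equal(s$lvr[1], 55.3)
  expect_equal(nrow(s), 2)
  # zero reference price zeroes the recovery
  pt0 <- price_table("x", c(FAS = 1, "1C" = 1e-12, "2C" = 1, "3C" = 1))
  expect_lt(score_trees(trees, prices = pt0)$lvr[1], 1e-9)
})
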