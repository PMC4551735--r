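# small shared fixture: additive response over two informative predictors
# plus noise columns
make_brt_data <- function(n = 600, noise_sd = 0.5, seed = 51) {
  set.seed(seed)
  data.frame(
    x1 = stats::runif(n, -2, 2),
    x2 = stats::runif(n, -2, 2),
    n1 = stats::rnorm(n),
    n2 = stats::rnorm(n),
    n3 = stats::rnorm(n),
    y = NA
  ) -> d
  d$y <- 3 * sin(d$x1) + 2 * d$x2 + stats::rnorm(n, 0, noise_sd)
  d
}

test_that("train/validation split is disjoint, exhaustive and reproducible", {
  d <- make_brt_data(100)
  sp <- split_train_validate(d, 0.7, seed = 3)
  expect_equal(nrow(sp$train), 70)
  expect_equal(nrow(sp$validate), 30)
  expect_length(intersect(rownames(sp$train), rownames(sp$validate)), 0)
  expect_setequal(c(rownames(sp$train), rownames(sp$validate)), rownames(d))
  sp2 <- split_train_validate(d, 0.7, seed = 3)
  expect_identical(sp, sp2)
  expect_error(split_train_validate(d, 1.2), "fraction")
  expect_error(split_train_validate(d[1:5, ], 0.7), "10 rows")
})

test_that("D-squared and RMSE agree with hand-computed oracles", {
  obs <- c(1, 2, 3)
  expect_equal(d_squared(obs, rep(2, 3)), 0)
  expect_equal(d_squared(obs, obs), 1)
  expect_equal(d_squared(obs, c(1, 2, 4)), 0.5)
  expect_error(d_squared(c(2, 2), c(1, 2)), "zero total deviance")
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
})

test_that("a constant response yields an intercept-only fit with D-squared 0", {
  d <- make_brt_data(60)
  d$y <- 42
  f <- fit_brt(d, "y", c("x1", "x2", "n1"),
               brt_config(min_trees = 10, max_trees = 20, cv_folds = 3))
  expect_true(all(predict(f, d) == 42))
  expect_equal(f$d_squared, 0)
})

test_that("boosting drives validation RMSE near zero on a noiseless step function", {
  set.seed(52)
  d <- data.frame(x1 = stats::runif(400), x2 = stats::runif(400))
  d$y <- ifelse(d$x1 > 0.5, 10, 0)
  sp <- split_train_validate(d, 0.7, seed = 1)
  f <- fit_brt(sp$train, "y", c("x1", "x2"),
               brt_config(tree_complexity = 1, learning_rate = 0.1,
                          min_trees = 50, max_trees = 300, cv_folds = 3,
                          seed = 2),
               validate = sp$validate)
  expect_lt(f$rmse, 0.5)
  expect_gt(f$d_squared, 0.99)
})

test_that("fits are seed-deterministic and bagging varies across seeds", {
  d <- make_brt_data(200)
  cfg <- brt_config(min_trees = 20, max_trees = 40, cv_folds = 3, seed = 5)
  f1 <- fit_brt(d, "y", c("x1", "x2", "n1"), cfg)
  f2 <- fit_brt(d, "y", c("x1", "x2", "n1"), cfg)
  expect_identical(predict(f1, d), predict(f2, d))
  cfg2 <- cfg
  cfg2$seed <- 6L
  f3 <- fit_brt(d, "y", c("x1", "x2", "n1"), cfg2)
  expect_false(identical(predict(f1, d), predict(f3, d)))
})

test_that("relative influence is non-negative, sums to 100, tracks information", {
  d <- make_brt_data(2000, seed = 53)
  cfg <- brt_config(tree_complexity = 2, learning_rate = 0.1,
                    min_trees = 50, max_trees = 120, cv_folds = 3, seed = 7)
  f <- fit_brt(d, "y", c("x1", "x2", "n1", "n2", "n3"), cfg)
  infl <- relative_influence(f)
  expect_true(all(infl >= 0))
  expect_equal(sum(infl), 100, tolerance = 1e-8)
  # every pure-noise predictor scores below every informative one
  expect_lt(max(infl[c("n1", "n2", "n3")]), min(infl[c("x1", "x2")]))
  # single informative predictor takes (almost) all the influence
  d2 <- d
  d2$y <- 4 * d2$x1 + stats::rnorm(nrow(d2), 0, 0.01)
  f2 <- fit_brt(d2, "y", c("x1", "n1", "n2"), cfg)
  expect_gt(relative_influence(f2)[["x1"]], 95)
})

test_that("partial dependence recovers additive component shapes", {
  d <- make_brt_data(2000, noise_sd = 0.2, seed = 54)
  cfg <- brt_config(tree_complexity = 2, learning_rate = 0.1,
                    min_trees = 80, max_trees = 200, cv_folds = 3, seed = 8)
  f <- fit_brt(d, "y", c("x1", "x2", "n1"), cfg)
  pd1 <- partial_dependence(f, "x1", grid_size = 30)
  expect_equal(range(pd1$value), range(d$x1))
  expect_gt(cor(pd1$partial_effect, 3 * sin(pd1$value)), 0.9)
  pd2 <- partial_dependence(f, "x2", grid_size = 30)
  expect_gt(cor(pd2$partial_effect, pd2$value), 0.9)
  expect_error(partial_dependence(f, "nope"), "unknown predictor")
  # constant model gives a flat curve
  dc <- d
  dc$y <- 7
  fc <- fit_brt(dc, "y", c("x1", "x2"),
                brt_config(min_trees = 5, max_trees = 10, cv_folds = 3))
  pdc <- partial_dependence(fc, "x1")
  expect_true(all(pdc$partial_effect == 7))
})

test_that("grid search evaluates the full grid and ranks by cv deviance", {
  d <- make_brt_data(300, seed = 55)
  cfg <- brt_config(min_trees = 10, max_trees = 30, cv_folds = 3, seed = 9)
  gs <- grid_search(d, "y", c("x1", "x2", "n1"),
                    tc_grid = c(1, 2), lr_grid = c(0.1, 0.05, 0.01), cfg)
  expect_equal(nrow(gs$leaderboard), 6)
  lb <- gs$leaderboard[order(gs$leaderboard$rank), ]
  lb <- lb[!is.na(lb$rank), ]
  expect_true(all(diff(lb$cv_deviance) >= 0))
  expect_equal(gs$best$config$tree_complexity, lb$tc[1])
  # grid of size one returns that model
  gs1 <- grid_search(d, "y", c("x1", "x2", "n1"),
                     tc_grid = 2, lr_grid = 0.1, cfg)
  expect_equal(nrow(gs1$leaderboard), 1)
  expect_equal(gs1$best$config$learning_rate, 0.1)
  expect_error(grid_search(d, "y", c("x1", "x2"), numeric(0), 0.1, cfg),
               "empty grid")
})

test_that("simplification drops noise predictors but keeps informative ones", {
  d <- make_brt_data(2000, noise_sd = 0.3, seed = 56)
  cfg <- brt_config(tree_complexity = 2, learning_rate = 0.1,
                    min_trees = 50, max_trees = 120, cv_folds = 3, seed = 10)
  f <- fit_brt(d, "y", c("x1", "x2", "n1", "n2", "n3"), cfg)
  s <- simplify_model(f)
  expect_true(all(c("x1", "x2") %in% s$retained))
  expect_true(length(s$dropped) >= 2)  # at least two noise columns gone
  # the reduced model predicts about as well as the full one
  expect_lt(s$cv_deviance, f$cv_deviance + 3 * f$cv_deviance_se)
})
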