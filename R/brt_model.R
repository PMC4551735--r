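#' Boosted regression tree configuration
#'
#' Tuning surface for the stochastic gradient boosting of plot LVR: tree
#' complexity (interaction depth of each tree), learning rate (shrinkage per
#' tree), bag fraction 0.5 (each iteration fits to a random 50% of the
#' training data, drawn without replacement), squared-error loss, and a
#' minimum ensemble size. The optimal number of trees is chosen by k-fold
#' cross-validated deviance on the training set.
#'
#' @param tree_complexity interaction depth, typically in \{1, 2, 5, 7, 10\}.
#' @param learning_rate shrinkage in \[0.0001, 0.1\].
#' @param bag_fraction subsampling fraction per iteration (0, 1\].
#' @param min_trees minimum admissible ensemble size.
#' @param max_trees upper bound on ensemble size searched.
#' @param train_fraction fraction of data assigned to training by
#'   [split_train_validate()].
#' @param cv_folds folds for cross-validated tree-count selection.
#' @param seed integer RNG seed.
#' @return An object of class `brt_config`.
#' @export
brt_config <- function(tree_complexity = 5, learning_rate = 0.01,
                       bag_fraction = 0.5, min_trees = 1000,
                       max_trees = 10 * min_trees, train_fraction = 0.7,
                       cv_folds = 10, seed = 1L) {
  if (bag_fraction <= 0 || bag_fraction > 1)
    stop("brt_config: bag_fraction must be in (0, 1]")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("brt_config: train_fraction must be in (0, 1)")
  if (min_trees < 1) stop("brt_config: min_trees must be >= 1")
  if (learning_rate <= 0) stop("brt_config: learning_rate must be positive")
  structure(list(tree_complexity = tree_complexity,
                 learning_rate = learning_rate, bag_fraction = bag_fraction,
                 min_trees = as.integer(min_trees),
                 max_trees = as.integer(max_trees),
                 train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "brt_config")
}

#' Random train/validation split
#'
#' Disjoint, exhaustive split with \eqn{\lfloor f n \rfloor} training rows,
#' reproducible per seed.
#'
#' @param data data frame with >= 10 rows.
#' @param fraction training fraction in (0, 1).
#' @param seed integer RNG seed.
#' @return List with `train` and `validate` data frames.
#' @export
split_train_validate <- function(data, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("split_train_validate: fraction must be in (0, 1)")
  n <- nrow(data)
  if (n < 10) stop("split_train_validate: need at least 10 rows")
  idx <- local_seed(seed, sample(n, floor(fraction * n)))
  list(train = data[sort(idx), , drop = FALSE],
       validate = data[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Proportion of deviance explained
#'
#' Under squared-error loss, \eqn{D^2 = 1 - \sum(y - \hat y)^2 / \sum(y -
#' \bar y)^2}: 1 for perfect prediction, 0 for predicting the mean.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return D-squared.
#' @export
d_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("d_squared: need equal-length vectors of length >= 2")
  tot <- sum((observed - mean(observed))^2)
  if (tot == 0) stop("d_squared: zero total deviance")
  1 - sum((observed - predicted)^2) / tot
}

#' Root mean squared error
#' @param observed,predicted numeric vectors of equal length.
#' @return RMSE in the response's units.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("rmse: length mismatch")
  sqrt(mean((observed - predicted)^2))
}

# Build the xgboost design matrix: numeric columns as-is, factors/characters
# as integer level codes (recorded for partial dependence grids).
brt_design <- function(data, predictors) {
  levels_map <- list()
  cols <- lapply(predictors, function(p) {
    v <- data[[p]]
    if (is.factor(v) || is.character(v)) {
      f <- if (is.factor(v)) v else factor(v)
      levels_map[[p]] <<- levels(f)
      as.numeric(f)
    } else as.numeric(v)
  })
  x <- do.call(cbind, cols)
  colnames(x) <- predictors
  list(x = x, levels = levels_map)
}

#' Fit a stochastic gradient boosted regression tree model
#'
#' Fits an ensemble of shallow regression trees by forward stage-wise
#' boosting with squared-error loss, interaction depth `tree_complexity`,
#' shrinkage `learning_rate`, and 50% subsampling without replacement per
#' iteration. The ensemble size is chosen by cross-validated deviance on the
#' training data (capped at `max_trees`); when a validation set is supplied,
#' D-squared and RMSE are computed on it.
#'
#' A constant response yields an intercept-only fit (all predictions equal
#' the constant, D-squared defined as 0).
#'
#' @param train training data frame.
#' @param response name of the numeric response column.
#' @param predictors character vector of predictor columns (>= 2).
#' @param config a [brt_config()].
#' @param validate optional validation data frame for out-of-sample metrics.
#' @return Object of class `brt_fit`: the xgboost booster, config, `n_trees`,
#'   `cv_deviance` (mean held-out squared error at `n_trees`) and its
#'   standard error, `d_squared`, `rmse`, `influence`, predictor metadata.
#' @export
fit_brt <- function(train, response, predictors, config = brt_config(),
                    validate = NULL) {
  stopifnot(inherits(config, "brt_config"))
  if (!is.numeric(train[[response]]))
    stop("fit_brt: response must be numeric")
  if (length(predictors) < 2)
    stop("fit_brt: need at least 2 predictors")
  y <- train[[response]]
  if (stats::var(y) == 0) {
    fit <- structure(list(constant = mean(y), config = config,
                          n_trees = 0L, response = response,
                          predictors = predictors,
                          d_squared = 0, rmse = 0,
                          cv_deviance = 0, cv_deviance_se = 0,
                          influence = stats::setNames(
                            rep(100 / length(predictors), length(predictors)),
                            predictors),
                          train = train),
                     class = "brt_fit")
    if (!is.null(validate))
      fit$rmse <- rmse(validate[[response]], rep(mean(y), nrow(validate)))
    return(fit)
  }
  des <- brt_design(train, predictors)
  params <- list(objective = "reg:squarederror",
                 base_score = mean(y),
                 max_depth = config$tree_complexity,
                 eta = config$learning_rate,
                 subsample = config$bag_fraction,
                 sampling_method = "uniform",
                 lambda = 0, nthread = 1,
                 seed = config$seed)
  dtrain <- xgboost::xgb.DMatrix(des$x, label = y)
  cv <- local_seed(config$seed,
    xgboost::xgb.cv(params = params, data = dtrain,
                    nrounds = config$max_trees, nfold = config$cv_folds,
                    early_stopping_rounds = max(20, config$min_trees %/% 10),
                    verbose = 0))
  log <- cv$evaluation_log
  best <- which.min(log$test_rmse_mean)
  n_trees <- max(best, min(config$min_trees, nrow(log)))
  booster <- local_seed(config$seed,
    xgboost::xgb.train(params = params, data = dtrain,
                       nrounds = n_trees, verbose = 0))
  fit <- structure(list(booster = booster, config = config,
                        n_trees = as.integer(n_trees),
                        response = response, predictors = predictors,
                        levels = des$levels,
                        cv_deviance = log$test_rmse_mean[n_trees]^2,
                        cv_deviance_se = 2 * log$test_rmse_mean[n_trees] *
                          log$test_rmse_std[n_trees] / sqrt(config$cv_folds),
                        cv_best_iter = as.integer(best),
                        train = train),
                   class = "brt_fit")
  fit$influence <- relative_influence(fit)
  if (!is.null(validate)) {
    pred <- predict(fit, validate)
    fit$d_squared <- d_squared(validate[[response]], pred)
    fit$rmse <- rmse(validate[[response]], pred)
  } else {
    pred <- predict(fit, train)
    fit$d_squared <- d_squared(y, pred)
    fit$rmse <- rmse(y, pred)
  }
  fit
}

#' @export
predict.brt_fit <- function(object, newdata, ...) {
  if (!is.null(object$constant))
    return(rep(object$constant, nrow(newdata)))
  x <- brt_design(newdata, object$predictors)$x
  # reuse training factor codings
  for (p in names(object$levels)) {
    v <- newdata[[p]]
    f <- factor(as.character(v), levels = object$levels[[p]])
    x[, p] <- as.numeric(f)
  }
  predict(object$booster, xgboost::xgb.DMatrix(x))
}

#' @export
print.brt_fit <- function(x, ...) {
  cat("Boosted regression tree fit\n")
  cat(sprintf("  trees: %d  tc: %s  lr: %g  bag fraction: %g\n",
              x$n_trees, x$config$tree_complexity, x$config$learning_rate,
              x$config$bag_fraction))
  if (!is.null(x$d_squared))
    cat(sprintf("  D-squared: %.3f  RMSE: %.3f\n", x$d_squared, x$rmse))
  top <- sort(x$influence, decreasing = TRUE)
  cat("  top influences (%):",
      paste(sprintf("%s %.1f", names(top)[seq_len(min(5, length(top)))],
                    top[seq_len(min(5, length(top)))]), collapse = ", "), "\n")
  invisible(x)
}

#' Relative influence of predictors
#'
#' For each predictor, sums the squared-error improvement (gain) of every
#' split made on it across all trees of the ensemble, then rescales so the
#' influences sum to 100. Predictors never selected for splitting score 0.
#'
#' @param fit a [fit_brt()] result.
#' @return Named numeric vector of percentages summing to 100.
#' @export
relative_influence <- function(fit) {
  if (!inherits(fit, "brt_fit")) stop("relative_influence: not a brt_fit")
  if (!is.null(fit$constant)) return(fit$influence)
  tr <- as.data.frame(xgboost::xgb.model.dt.tree(model = fit$booster))
  splits <- tr[tr$Feature != "Leaf", , drop = FALSE]
  gain <- tapply(splits$Gain, splits$Feature, sum)
  infl <- stats::setNames(rep(0, length(fit$predictors)), fit$predictors)
  infl[names(gain)] <- gain
  if (sum(infl) == 0) return(infl)  # no informative splits
  100 * infl / sum(infl)
}

#' Grid search over tree complexity and learning rate
#'
#' Fits every (tc, lr) combination, keeps those whose cross-validated optimal
#' ensemble size respects the minimum-trees constraint, and ranks candidates
#' by cross-validated predictive deviance (ascending). Ties prefer the
#' slowest learning rate, which shrinks each tree's contribution and gives
#' more reliable response estimates.
#'
#' @param train training data frame.
#' @param response,predictors as in [fit_brt()].
#' @param tc_grid,lr_grid candidate tree complexities and learning rates.
#' @param config base [brt_config()] (seed, bag fraction, tree limits).
#' @return List with `best` (the winning `brt_fit`) and `leaderboard` (one
#'   row per combination: tc, lr, n_trees, cv_deviance, meets_min_trees,
#'   rank among admissible candidates).
#' @export
grid_search <- function(train, response, predictors,
                        tc_grid = c(1, 2, 5, 7, 10),
                        lr_grid = c(0.1, 0.05, 0.01, 0.005, 0.001, 5e-4, 1e-4),
                        config = brt_config()) {
  if (!length(tc_grid) || !length(lr_grid))
    stop("grid_search: empty grid")
  grid <- expand.grid(tc = tc_grid, lr = lr_grid)
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg$tree_complexity <- grid$tc[i]
    cfg$learning_rate <- grid$lr[i]
    f <- fit_brt(train, response, predictors, cfg)
    fits[[i]] <- f
    rows[[i]] <- data.frame(tc = grid$tc[i], lr = grid$lr[i],
                            n_trees = f$n_trees,
                            cv_deviance = f$cv_deviance,
                            meets_min_trees = f$n_trees >= cfg$min_trees &&
                              (is.null(f$cv_best_iter) ||
                               f$cv_best_iter >= cfg$min_trees))
  }
  lb <- do.call(rbind, rows)
  ok <- which(lb$meets_min_trees)
  if (!length(ok))
    stop("grid_search: no combination reaches the minimum tree count; ",
         "use a smaller learning rate")
  # rank by deviance; ties prefer the slowest learning rate
  ord <- ok[order(lb$cv_deviance[ok], lb$lr[ok])]
  lb$rank <- NA_integer_
  lb$rank[ord] <- seq_along(ord)
  list(best = fits[[ord[1]]], leaderboard = lb)
}

#' Partial dependence of the fitted model on one predictor
#'
#' Friedman's partial dependence: for each grid value v, the average model
#' prediction over the training rows with the predictor forced to v. Numeric
#' predictors use an equally spaced grid over their observed range;
#' categorical predictors use their levels.
#'
#' @param fit a [fit_brt()] result.
#' @param predictor predictor name (must be in the model).
#' @param grid_size number of grid points for numeric predictors.
#' @return Data frame with `value` and `partial_effect`.
#' @export
partial_dependence <- function(fit, predictor, grid_size = 25) {
  if (!inherits(fit, "brt_fit")) stop("partial_dependence: not a brt_fit")
  if (!predictor %in% fit$predictors)
    stop("partial_dependence: unknown predictor '", predictor, "'")
  tr <- fit$train
  v <- tr[[predictor]]
  grid <- if (is.factor(v) || is.character(v)) {
    if (is.factor(v)) levels(v) else sort(unique(v))
  } else {
    seq(min(v), max(v), length.out = grid_size)
  }
  eff <- vapply(grid, function(g) {
    tmp <- tr
    tmp[[predictor]] <- if (is.factor(v)) factor(g, levels = levels(v)) else g
    mean(predict(fit, tmp))
  }, numeric(1))
  data.frame(value = grid, partial_effect = eff,
             stringsAsFactors = FALSE)
}

#' Drop uninformative predictors from a fitted ensemble
#'
#' Iteratively removes the lowest-influence predictor and refits; a removal
#' is kept while the cross-validated predictive deviance rises by less than
#' `tolerance_se` standard errors of the current model's cv deviance. Stops
#' at the first rejected removal or at two remaining predictors.
#'
#' @param fit a [fit_brt()] result.
#' @param tolerance_se allowed deviance increase, in cv standard errors.
#' @return The reduced `brt_fit` (possibly the original), with
#'   `retained` = its predictor set and `dropped` = removed predictors.
#' @export
simplify_model <- function(fit, tolerance_se = 1) {
  if (!inherits(fit, "brt_fit")) stop("simplify_model: not a brt_fit")
  current <- fit
  dropped <- character(0)
  while (length(current$predictors) > 2) {
    cand <- names(sort(current$influence))[1]
    keep <- setdiff(current$predictors, cand)
    trial <- fit_brt(current$train, current$response, keep, current$config)
    if (trial$cv_deviance <=
        current$cv_deviance + tolerance_se * current$cv_deviance_se) {
      dropped <- c(dropped, cand)
      current <- trial
    } else break
  }
  current$retained <- current$predictors
  current$dropped <- dropped
  current
}
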