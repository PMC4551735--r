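#' Default quality-index model coefficients
#'
#' Coefficients of the recalibrated quality-index (QI) model, fitted to a
#' 96-tree yellow birch / sugar maple sawing study. The model expresses the QI
#' of a tree as a sum of per-grade terms, one for each log grade (F1--F4) with
#' non-zero volume:
#' \deqn{QI = \sum_{i : V_{Fi} > 0} \left(\beta_i + \beta_1 V_{Fi}^2 / V_g\right)}
#' where \eqn{V_{Fi}} is the log volume in grade Fi (m\eqn{^3}) and \eqn{V_g}
#' the gross volume (m\eqn{^3}). `beta1` is the common slope on the squared
#' grade volume; `beta0`, `beta2`, `beta3`, `beta4` are the grade intercepts
#' for F1, F2, F3 and F4 respectively, declining with grade quality.
#'
#' @param beta0,beta1,beta2,beta3,beta4 model coefficients (dimensionless).
#' @return An object of class `qi_params`.
#' @export
#' @examples
#' qi_params()          # recalibrated defaults
#' qi_params(beta1 = 0) # grade intercepts only
qi_params <- function(beta0 = 0.64, beta1 = 1.09, beta2 = 0.60,
                      beta3 = 0.49, beta4 = 0.48) {
  p <- c(beta0 = beta0, beta1 = beta1, beta2 = beta2,
         beta3 = beta3, beta4 = beta4)
  if (!all(is.finite(p))) stop("qi_params: all coefficients must be finite")
  structure(as.list(p), class = "qi_params")
}

#' Default sawn-wood yield model coefficients
#'
#' Coefficients of the linear sawn-wood yield model
#' \eqn{V_{sw} = \gamma_0 + \gamma_1 V_g}, predicting the volume of boards
#' (m\eqn{^3}) sawable from a tree of gross volume \eqn{V_g}. Defaults are the
#' recalibrated sawing-study estimates.
#'
#' @param gamma0 intercept (m^3).
#' @param gamma1 slope (dimensionless).
#' @return An object of class `vsw_params`.
#' @export
vsw_params <- function(gamma0 = -0.01, gamma1 = 0.58) {
  if (!is.finite(gamma0) || !is.finite(gamma1))
    stop("vsw_params: coefficients must be finite")
  structure(list(gamma0 = gamma0, gamma1 = gamma1), class = "vsw_params")
}

#' Species price table
#'
#' Market prices per NHLA board class (FAS, 1C, 2C, 3C) in $US/m^3, with 1C as
#' the reference class by convention. `default_price_table()` returns prices
#' whose ratios match the 2008--2012 relative price structure for the two
#' target species, anchored at a reference 1C price of 140 $US/m^3 (chosen so
#' that typical scored trees land in the observed provincial LVR range of
#' roughly 85--160 $US/m^3).
#'
#' @param species species label.
#' @param prices named numeric vector of board-class prices ($US/m^3), all > 0.
#' @param reference name of the reference class (must be in `prices`).
#' @return An object of class `price_table`.
#' @export
price_table <- function(species, prices, reference = "1C") {
  if (!is.numeric(prices) || is.null(names(prices)))
    stop("price_table: prices must be a named numeric vector")
  if (any(!is.finite(prices)) || any(prices <= 0))
    stop("price_table: all prices must be positive and finite")
  if (!reference %in% names(prices))
    stop("price_table: reference class '", reference, "' not present in prices")
  structure(list(species = species, prices = prices, reference = reference),
            class = "price_table")
}

#' @rdname price_table
#' @export
default_price_table <- function(species = c("yellow_birch", "sugar_maple")) {
  species <- match.arg(species)
  rel <- switch(species,
    yellow_birch = c(FAS = 1.81, "1C" = 1.00, "2C" = 0.70, "3C" = 0.25),
    sugar_maple  = c(FAS = 1.65, "1C" = 1.00, "2C" = 0.69, "3C" = 0.37))
  price_table(species, rel * 140, reference = "1C")
}

#' Relative board-class prices
#'
#' Divides each board-class price by the reference-class (1C) price, giving the
#' dimensionless relative prices RP_c used in the yield-weighted quality index.
#' The reference class has ratio exactly 1.
#'
#' @param prices a [price_table()].
#' @return Named numeric vector of price ratios.
#' @export
#' @examples
#' compute_relative_prices(default_price_table("yellow_birch"))
compute_relative_prices <- function(prices) {
  stopifnot(inherits(prices, "price_table"))
  ref <- prices$prices[[prices$reference]]
  out <- prices$prices / ref
  out[prices$reference] <- 1.0
  out
}

#' Quality index from board-class yields
#'
#' The legacy definition of the quality index: the sum over board classes of
#' sawn-wood yield times relative price, \eqn{QI = \sum_c Y_c RP_c}.
#'
#' @param yields named numeric vector of sawn-volume proportions per board
#'   class, each in \[0, 1\], summing to at most 1.
#' @param ratios named numeric vector of relative prices (see
#'   [compute_relative_prices()]); must cover every class in `yields`.
#' @return The quality index (dimensionless).
#' @export
qi_from_yields <- function(yields, ratios) {
  if (any(yields < 0)) stop("qi_from_yields: negative yield")
  if (sum(yields) > 1 + 1e-8) stop("qi_from_yields: yields sum to more than 1")
  missing <- setdiff(names(yields), names(ratios))
  if (length(missing))
    stop("qi_from_yields: no price ratio for class(es): ",
         paste(missing, collapse = ", "))
  sum(yields * ratios[names(yields)])
}

#' Predict the quality index from per-grade log volumes
#'
#' Applies the recalibrated QI model: each log grade with non-zero volume
#' contributes its grade intercept plus the common slope times the squared
#' grade volume over gross volume. Grades with zero volume contribute nothing;
#' a tree with no graded volume at all is an error.
#'
#' @param vf1,vf2,vf3,vf4 log volume (m^3) in grades F1..F4; vectors are
#'   recycled to a common length.
#' @param vg gross volume (m^3), > 0.
#' @param params a [qi_params()] object.
#' @return Numeric vector of quality indices.
#' @export
#' @examples
#' predict_qi(vf1 = 0.5, vf2 = 0, vf3 = 0, vf4 = 0, vg = 0.5)  # 1.185
predict_qi <- function(vf1, vf2, vf3, vf4, vg, params = qi_params()) {
  stopifnot(inherits(params, "qi_params"))
  n <- max(length(vf1), length(vf2), length(vf3), length(vf4), length(vg))
  vf <- cbind(rep_len(vf1, n), rep_len(vf2, n), rep_len(vf3, n), rep_len(vf4, n))
  vg <- rep_len(vg, n)
  if (any(vf < 0)) stop("predict_qi: grade volumes must be non-negative")
  if (any(vg <= 0)) stop("predict_qi: vg must be positive")
  if (any(rowSums(vf) > vg + 1e-8))
    stop("predict_qi: graded volume exceeds gross volume")
  if (any(rowSums(vf) == 0)) stop("predict_qi: no graded volume")
  intercepts <- c(params$beta0, params$beta2, params$beta3, params$beta4)
  present <- vf > 0
  rowSums(present * (rep(intercepts, each = n) + params$beta1 * vf^2 / vg))
}

#' Predict sawn-wood yield from gross volume
#'
#' Linear yield model \eqn{V_{sw} = \gamma_0 + \gamma_1 V_g}, clamped at zero:
#' the fitted intercept is slightly negative, so very small trees would
#' otherwise predict a negative board volume.
#'
#' @param vg gross volume (m^3), > 0.
#' @param params a [vsw_params()] object.
#' @return Sawn-wood volume (m^3), >= 0.
#' @export
predict_vsw <- function(vg, params = vsw_params()) {
  stopifnot(inherits(params, "vsw_params"))
  if (any(vg <= 0)) stop("predict_vsw: vg must be positive")
  pmax(0, params$gamma0 + params$gamma1 * vg)
}

#' Lumber value of a tree
#'
#' \eqn{LV = QI \cdot P \cdot V_{sw}}: quality index times reference-class
#' board price times sawn-wood volume.
#'
#' @param qi quality index (dimensionless, >= 0).
#' @param price_ref reference-class (1C) board price ($US/m^3, >= 0).
#' @param vsw sawn-wood volume (m^3, >= 0).
#' @return Lumber value ($US).
#' @export
compute_lv <- function(qi, price_ref, vsw) {
  if (any(qi < 0) || any(price_ref < 0) || any(vsw < 0))
    stop("compute_lv: inputs must be non-negative")
  qi * price_ref * vsw
}

#' Lumber value recovery
#'
#' LVR is lumber value per unit volume of round wood, $US/m^3: the study's
#' indicator of timber quality, comparable across tree sizes.
#'
#' @param total_lv lumber value ($US).
#' @param roundwood_volume total roundwood volume (m^3), > 0.
#' @return LVR ($US/m^3).
#' @export
compute_lvr <- function(total_lv, roundwood_volume) {
  if (any(roundwood_volume <= 0))
    stop("compute_lvr: roundwood volume must be positive")
  total_lv / roundwood_volume
}

#' Fit the sawn-wood yield model
#'
#' Ordinary least squares fit of \eqn{V_{sw} = \gamma_0 + \gamma_1 V_g}.
#'
#' @param pairs data frame with columns `vg` and `vsw`.
#' @return A list with `params` ([vsw_params()]), `se` (standard errors),
#'   `adj_r_squared`, and the underlying `lm` fit.
#' @export
fit_vsw_model <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("vg", "vsw") %in% names(pairs)))
  if (nrow(pairs) < 3) stop("fit_vsw_model: need at least 3 observations")
  if (length(unique(pairs$vg)) < 2)
    stop("fit_vsw_model: vg values are all equal; rank-deficient design")
  fit <- stats::lm(vsw ~ vg, data = pairs)
  cf <- stats::coef(fit)
  list(params = vsw_params(gamma0 = unname(cf[1]), gamma1 = unname(cf[2])),
       se = unname(sqrt(diag(stats::vcov(fit)))),
       adj_r_squared = summary(fit)$adj.r.squared,
       fit = fit)
}

#' Fit the quality-index model
#'
#' Linear least squares on the design implied by conditional grade-term
#' inclusion: four grade-presence indicator columns (the grade intercepts) and
#' one pooled regressor \eqn{\sum_i 1\{V_{Fi} > 0\} V_{Fi}^2 / V_g} (the common
#' slope). Trees in which every grade is present make the four intercepts
#' jointly unidentifiable (only their sum is estimable); the fit fails with an
#' explicit message naming the aliased parameters.
#'
#' @param obs data frame with columns `vf1`..`vf4`, `vg`, `qi` (observed
#'   quality index).
#' @return A list with `params` ([qi_params()]), `se` (standard errors in the
#'   order beta0, beta1, beta2, beta3, beta4), `adj_r_squared`, and `fit`.
#' @export
fit_qi_model <- function(obs) {
  need <- c("vf1", "vf2", "vf3", "vf4", "vg", "qi")
  stopifnot(is.data.frame(obs), all(need %in% names(obs)))
  if (nrow(obs) < 6) stop("fit_qi_model: need at least 6 observations")
  vf <- as.matrix(obs[, c("vf1", "vf2", "vf3", "vf4")])
  if (any(vf < 0) || any(obs$vg <= 0))
    stop("fit_qi_model: invalid grade or gross volumes")
  ind <- (vf > 0) * 1
  pooled <- rowSums(ind * vf^2 / obs$vg)
  X <- cbind(f1 = ind[, 1], f2 = ind[, 2], f3 = ind[, 3], f4 = ind[, 4],
             slope = pooled)
  if (qr(X)$rank < ncol(X)) {
    fit0 <- stats::lm.fit(X, obs$qi)
    aliased <- colnames(X)[is.na(fit0$coefficients)]
    stop("fit_qi_model: rank-deficient design; unidentifiable parameter(s): ",
         paste(if (length(aliased)) aliased else "intercepts", collapse = ", "))
  }
  df <- as.data.frame(X)
  df$qi <- obs$qi
  fit <- stats::lm(qi ~ f1 + f2 + f3 + f4 + slope - 1, data = df)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  # adjusted R^2 against the centred total SS (the no-intercept lm summary
  # would use the uncentred total and overstate the fit)
  n <- nrow(df)
  p <- ncol(X)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((obs$qi - mean(obs$qi))^2)
  adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  list(params = qi_params(beta0 = unname(cf["f1"]), beta1 = unname(cf["slope"]),
                          beta2 = unname(cf["f2"]), beta3 = unname(cf["f3"]),
                          beta4 = unname(cf["f4"])),
       se = unname(se[c("f1", "slope", "f2", "f3", "f4")]),
       adj_r_squared = adj,
       fit = fit)
}

#' Score trees through the full lumber-value chain
#'
#' Chains the recalibrated models for each tree: quality index from grade
#' volumes, sawn-wood yield from gross volume, lumber value, and lumber value
#' recovery per unit roundwood volume.
#'
#' @param trees data frame with columns `vf1`..`vf4`, `vg`, `roundwood_m3`
#'   (and optionally `plot_id`, `species`, carried through).
#' @param qi_par a [qi_params()] object.
#' @param vsw_par a [vsw_params()] object.
#' @param prices a [price_table()]; its reference-class price is P.
#' @return `trees` with columns `qi`, `vsw`, `lv`, `lvr` appended, rows in
#'   input order.
#' @export
#' @examples
#' t1 <- data.frame(vf1 = 0.5, vf2 = 0, vf3 = 0, vf4 = 0,
#'                  vg = 0.5, roundwood_m3 = 0.6)
#' score_trees(t1)$lvr  # 112.575
score_trees <- function(trees, qi_par = qi_params(), vsw_par = vsw_params(),
                        prices = default_price_table("yellow_birch")) {
  need <- c("vf1", "vf2", "vf3", "vf4", "vg", "roundwood_m3")
  stopifnot(is.data.frame(trees), all(need %in% names(trees)))
  p_ref <- prices$prices[[prices$reference]]
  trees$qi <- predict_qi(trees$vf1, trees$vf2, trees$vf3, trees$vf4,
                         trees$vg, qi_par)
  trees$vsw <- predict_vsw(trees$vg, vsw_par)
  trees$lv <- compute_lv(trees$qi, p_ref, trees$vsw)
  trees$lvr <- compute_lvr(trees$lv, trees$roundwood_m3)
  trees
}
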