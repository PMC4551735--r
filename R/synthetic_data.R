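#' Specification of a synthetic sawing study
#'
#' Describes a simulated mill study of the kind used to recalibrate the
#' lumber-value models: trees of known gross volume are broken into graded log
#' volumes, and an observed quality index and sawn-wood volume are recorded.
#' Observations are drawn from the QI and Vsw models used as ground truth,
#' plus Gaussian noise. Defaults emulate the 96-tree yellow birch / sugar
#' maple study behind the recalibration: the noise standard deviations are set
#' so that refitting reproduces adjusted R-squared values of roughly 0.5 (QI)
#' and 0.97 (Vsw) at n = 96.
#'
#' @param n_logs number of sawing observations (trees).
#' @param vg_range range (m^3) of gross volumes, drawn uniformly.
#' @param grade_mix probability of each log grade F1..F4 being sampled when a
#'   tree's grades are drawn; must sum to 1.
#' @param qi_params,vsw_params ground-truth model parameters.
#' @param qi_noise_sd Gaussian noise sd on observed QI (dimensionless).
#' @param vsw_noise_sd Gaussian noise sd on observed Vsw (m^3).
#' @param seed integer RNG seed.
#' @return An object of class `sawing_study_spec`.
#' @export
sawing_study_spec <- function(n_logs = 96,
                              vg_range = c(0.2, 2.0),
                              grade_mix = c(F1 = 0.2, F2 = 0.3,
                                            F3 = 0.3, F4 = 0.2),
                              qi_params = lvrscape::qi_params(),
                              vsw_params = lvrscape::vsw_params(),
                              qi_noise_sd = 0.42,
                              vsw_noise_sd = 0.05,
                              seed = 1L) {
  if (length(n_logs) != 1 || n_logs < 1)
    stop("sawing_study_spec: invalid field 'n_logs'")
  if (length(vg_range) != 2 || any(vg_range <= 0) || diff(vg_range) < 0)
    stop("sawing_study_spec: invalid field 'vg_range' (must be positive interval)")
  if (length(grade_mix) != 4 || any(grade_mix < 0) ||
      abs(sum(grade_mix) - 1) > 1e-8)
    stop("sawing_study_spec: invalid field 'grade_mix' (must sum to 1)")
  if (qi_noise_sd < 0) stop("sawing_study_spec: invalid field 'qi_noise_sd'")
  if (vsw_noise_sd < 0) stop("sawing_study_spec: invalid field 'vsw_noise_sd'")
  structure(list(n_logs = as.integer(n_logs), vg_range = vg_range,
                 grade_mix = grade_mix, qi_params = qi_params,
                 vsw_params = vsw_params, qi_noise_sd = qi_noise_sd,
                 vsw_noise_sd = vsw_noise_sd, seed = as.integer(seed)),
            class = "sawing_study_spec")
}

#' Generate a synthetic sawing study
#'
#' Each tree receives a uniform gross volume, a random subset of one to three
#' log grades (sampled by `grade_mix`), and a random allocation of 50--95% of
#' its gross volume across the present grades. Observed QI and Vsw are the
#' ground-truth model values plus Gaussian noise; Vsw is clamped at zero.
#' Output is byte-identical for identical spec and seed.
#'
#' @param spec a [sawing_study_spec()].
#' @return Data frame with columns `vf1`..`vf4`, `vg`, `qi`, `vsw`.
#' @export
gen_sawing_study <- function(spec) {
  stopifnot(inherits(spec, "sawing_study_spec"))
  n <- spec$n_logs
  out <- local_seed(spec$seed, {
    vg <- stats::runif(n, spec$vg_range[1], spec$vg_range[2])
    vf <- matrix(0, n, 4)
    for (i in seq_len(n)) {
      k <- sample(1:3, 1)
      grades <- sample(1:4, k, prob = spec$grade_mix)
      w <- stats::rgamma(k, shape = 2)
      vf[i, grades] <- (w / sum(w)) * vg[i] * stats::runif(1, 0.5, 0.95)
    }
    qi_true <- predict_qi(vf[, 1], vf[, 2], vf[, 3], vf[, 4], vg,
                          spec$qi_params)
    vsw_true <- predict_vsw(vg, spec$vsw_params)
    data.frame(vf1 = vf[, 1], vf2 = vf[, 2], vf3 = vf[, 3], vf4 = vf[, 4],
               vg = vg,
               qi = qi_true + stats::rnorm(n, 0, spec$qi_noise_sd),
               vsw = pmax(0, vsw_true + stats::rnorm(n, 0, spec$vsw_noise_sd)))
  })
  out
}

#' Specification of a synthetic temporary-sample-plot network
#'
#' Describes a simulated provincial plot network with known ground truth: the
#' latent mean LVR of each plot is an additive function of a baseline, smooth
#' covariate effects, and planted circular cluster effects, plus a Gaussian
#' residual. Coordinates are planar projected metres. Trees are drawn per plot
#' (truncated Poisson, at least one sawlog-eligible tree) with grade volumes
#' constructed so that scoring them through the lumber-value chain recovers a
#' plot LVR close to the latent value.
#'
#' Default covariate effects mirror the directions reported for the study
#' system: LVR rises with stand structural diversity and basal area and falls
#' with merchantable stem count; the remaining generated covariates carry no
#' effect and act as noise predictors.
#'
#' @param n_plots number of plots (>= 1).
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in projected metres.
#' @param cluster_centres list of planted clusters, each
#'   `list(x=, y=, radius=, effect=)` (radius m, effect $US/m^3).
#' @param covariate_effects named list of functions mapping a generated
#'   covariate column to an additive LVR contribution ($US/m^3).
#' @param baseline_lvr baseline LVR ($US/m^3).
#' @param residual_sd plot-level residual sd ($US/m^3).
#' @param trees_per_plot Poisson mean for merchantable trees per plot
#'   (truncated below at 1).
#' @param seed integer RNG seed.
#' @return An object of class `tsp_sim_spec`.
#' @export
tsp_sim_spec <- function(n_plots = 2000,
                         extent = c(0, 20000, 0, 20000),
                         cluster_centres = list(),
                         covariate_effects = default_covariate_effects(),
                         baseline_lvr = 110,
                         residual_sd = 8,
                         trees_per_plot = 5,
                         seed = 1L) {
  if (length(n_plots) != 1 || n_plots < 1)
    stop("tsp_sim_spec: invalid field 'n_plots'")
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("tsp_sim_spec: invalid field 'extent' (degenerate rectangle)")
  for (cl in cluster_centres)
    if (is.null(cl$radius) || cl$radius <= 0)
      stop("tsp_sim_spec: invalid field 'cluster_centres' (radius must be > 0)")
  if (residual_sd < 0) stop("tsp_sim_spec: invalid field 'residual_sd'")
  structure(list(n_plots = as.integer(n_plots), extent = extent,
                 cluster_centres = cluster_centres,
                 covariate_effects = covariate_effects,
                 baseline_lvr = baseline_lvr, residual_sd = residual_sd,
                 trees_per_plot = trees_per_plot, seed = as.integer(seed)),
            class = "tsp_sim_spec")
}

#' @rdname tsp_sim_spec
#' @export
default_covariate_effects <- function() {
  list(
    struct_div_gen = function(x) 6 * (x - mean(x)) / stats::sd(x),
    basal_area     = function(x) 5 * (x - mean(x)) / stats::sd(x),
    stems_ha       = function(x) -5 * (x - mean(x)) / stats::sd(x)
  )
}

# Covariate columns generated for every plot. Continuous descriptors get
# plausible provincial-scale distributions; categorical codes are drawn from
# the declared vocabularies. Only the columns named in covariate_effects
# influence the latent LVR.
gen_plot_covariates <- function(n) {
  vocab <- plot_vocabularies()
  data.frame(
    age_class = sample(vocab$age_class, n, replace = TRUE),
    height_class = sample(vocab$height_class, n, replace = TRUE),
    density_class = sample(vocab$density_class, n, replace = TRUE),
    drainage_class = sample(vocab$drainage_class, n, replace = TRUE),
    ecotype = sample(vocab$ecotype, n, replace = TRUE),
    deposit = sample(vocab$deposit, n, replace = TRUE),
    basal_area = pmax(5, stats::rnorm(n, 25, 6)),        # m^2/ha
    stems_ha = pmax(50, stats::rnorm(n, 450, 120)),      # stems/ha
    struct_div_gen = pmax(1, stats::rnorm(n, 5, 1.2)),   # effective DBH classes
    slope = pmax(0, stats::rnorm(n, 10, 6)),             # %
    altitude = stats::runif(n, 100, 800),                # m
    temp_min = stats::rnorm(n, -0.5, 1.5),               # degC
    temp_mean = stats::rnorm(n, 3.5, 1.2),
    temp_max = stats::rnorm(n, 9, 1.2),
    precip = stats::rnorm(n, 1000, 120),                 # mm/yr
    snowfall = stats::rnorm(n, 300, 60),                 # mm water
    humidity = stats::rnorm(n, 72, 4),                   # %
    wind = stats::rnorm(n, 12, 3),                       # km/h
    growing_season = stats::rnorm(n, 180, 12),           # days
    evapo = stats::rnorm(n, 520, 40),                    # mm
    aridity = pmax(0, stats::rnorm(n, 60, 25)),          # mm deficit
    radiation = stats::rnorm(n, 4300, 180),              # MJ/m^2
    precip_days = stats::rnorm(n, 160, 12),
    clmax = stats::rnorm(n, 800, 250),                   # eq/ha/yr
    exceedance_dep = stats::rnorm(n, -100, 200)          # eq/ha/yr
  )
}

#' Generate a synthetic plot network with trees
#'
#' Places plots uniformly in the extent, computes each plot's latent mean LVR
#' (baseline + covariate effects + planted cluster effects), adds the plot
#' residual, and draws a tree list per plot whose grade volumes are solved
#' from the QI model so that volume-weighted tree scoring approximately
#' reproduces the plot's LVR. The plot table records the latent truth in
#' `lvr_true` (for validation only; never a predictor).
#'
#' @param spec a [tsp_sim_spec()].
#' @return List with `plots` (plot table: `plot_id`, `x`, `y`, covariates,
#'   `lvr_true`) and `trees` (tree table: `plot_id`, `species`, `dbh_cm`,
#'   `quality_class`, `vf1`..`vf4`, `vg`, `roundwood_m3`).
#' @export
gen_tsp_database <- function(spec) {
  stopifnot(inherits(spec, "tsp_sim_spec"))
  local_seed(spec$seed, {
    n <- spec$n_plots
    plots <- data.frame(
      plot_id = sprintf("P%05d", seq_len(n)),
      x = stats::runif(n, spec$extent[1], spec$extent[2]),
      y = stats::runif(n, spec$extent[3], spec$extent[4]))
    plots <- cbind(plots, gen_plot_covariates(n))

    latent <- rep(spec$baseline_lvr, n)
    for (nm in names(spec$covariate_effects)) {
      if (!nm %in% names(plots))
        stop("gen_tsp_database: covariate effect on unknown column '", nm, "'")
      latent <- latent + spec$covariate_effects[[nm]](plots[[nm]])
    }
    for (cl in spec$cluster_centres) {
      d <- sqrt((plots$x - cl$x)^2 + (plots$y - cl$y)^2)
      latent <- latent + ifelse(d <= cl$radius, cl$effect, 0)
    }
    plots$lvr_true <- latent + stats::rnorm(n, 0, spec$residual_sd)

    trees <- gen_trees_for_plots(plots, spec$trees_per_plot)
    list(plots = plots, trees = trees)
  })
}

# Draw a merchantable tree list per plot. Tree grade volumes are solved from
# the QI model so that each tree's LVR is close to the plot's realised LVR.
# Given a target QI, the number of log grades present is chosen greedily from
# the cumulative grade intercepts (a higher-quality tree carries logs of more
# grades, F1 first); the residual QI is met through the common slope term by
# splitting the graded volume equally: vf = sqrt(residual vg / (m beta1)),
# clamped so total graded volume stays below 90% of gross volume. Trees whose
# target lies below the lowest intercept get a single F4 log.
gen_trees_for_plots <- function(plots, lambda,
                                qi_par = qi_params(), vsw_par = vsw_params(),
                                p_ref = 140) {
  counts <- pmax(1, stats::rpois(nrow(plots), lambda))
  total <- sum(counts)
  plot_idx <- rep(seq_len(nrow(plots)), counts)
  species <- sample(c("yellow_birch", "sugar_maple"), total,
                    replace = TRUE, prob = c(0.4, 0.6))
  dbh <- stats::rlnorm(total, log(29), 0.18)
  # guarantee at least one sawlog-eligible tree per plot
  first <- !duplicated(plot_idx)
  dbh[first] <- pmax(dbh[first], 23.5)
  vg <- 0.00045 * dbh^2                      # coarse volume allometry (m^3)
  roundwood <- vg / 0.85
  vsw <- predict_vsw(vg, vsw_par)
  target_lvr <- plots$lvr_true[plot_idx] + stats::rnorm(total, 0, 3)
  qi_target <- pmax(0.1, target_lvr * roundwood / (p_ref * pmax(vsw, 1e-6)))
  intercepts <- c(qi_par$beta0, qi_par$beta2, qi_par$beta3, qi_par$beta4)
  cum_int <- cumsum(intercepts)              # 0.64 1.24 1.73 2.21
  m <- findInterval(qi_target, cum_int)      # grades present, F1..Fm
  vf <- matrix(0, total, 4)
  low <- m == 0                              # below beta0: single F4 log
  if (any(low)) {
    res <- pmax(0.01, qi_target[low] - qi_par$beta4)
    vf[cbind(which(low), 4)] <-
      pmin(sqrt(res * vg[low] / qi_par$beta1), 0.9 * vg[low])
  }
  for (mm in 1:4) {
    idx <- which(m == mm)
    if (!length(idx)) next
    res <- pmax(0.005, qi_target[idx] - cum_int[mm])
    each <- pmin(sqrt(res * vg[idx] / (mm * qi_par$beta1)),
                 0.9 * vg[idx] / mm)
    vf[idx, 1:mm] <- each                    # recycles column-major per grade
  }
  quality_class <- c("D", "D", "C", "B", "A")[m + 1]
  data.frame(plot_id = plots$plot_id[plot_idx], species = species,
             dbh_cm = dbh, quality_class = quality_class,
             vf1 = vf[, 1], vf2 = vf[, 2], vf3 = vf[, 3], vf4 = vf[, 4],
             vg = vg, roundwood_m3 = roundwood)
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
# state afterwards so generators do not perturb ambient randomness.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
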