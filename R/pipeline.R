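#' Pipeline configuration
#'
#' Assembles every knob of the end-to-end run: the synthetic-data specs (or
#' paths to existing tree/plot/sawing CSVs), the species to analyse, the
#' lumber-value parameter source (recalibrated defaults or a refit on the
#' sawing table), BRT tuning grids, hotspot band candidates, seeds, and the
#' output directory.
#'
#' @param sawing_spec a [sawing_study_spec()], or NULL to skip refitting.
#' @param tsp_spec a [tsp_sim_spec()] used when no input CSVs are given.
#' @param tree_csv,plot_csv optional paths to existing input tables.
#' @param species species to analyse.
#' @param refit_lumber_models logical; refit QI/Vsw on the sawing study
#'   instead of using the recalibrated defaults.
#' @param brt a [brt_config()].
#' @param tc_grid,lr_grid grids for [grid_search()]; NULL fits one model.
#' @param band_candidates hotspot band distances (m).
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed; stage seeds derive from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sawing_spec = sawing_study_spec(),
                            tsp_spec = tsp_sim_spec(),
                            tree_csv = NULL, plot_csv = NULL,
                            species = "yellow_birch",
                            refit_lumber_models = TRUE,
                            brt = brt_config(min_trees = 50, max_trees = 400,
                                             cv_folds = 5),
                            tc_grid = NULL, lr_grid = NULL,
                            band_candidates = seq(1000, 4000, by = 500),
                            out_dir = tempfile("lvr_run_"),
                            seed = 1L) {
  for (p in c(tree_csv, plot_csv))
    if (!file.exists(p)) stop("pipeline_config: input file not found: ", p)
  structure(list(sawing_spec = sawing_spec, tsp_spec = tsp_spec,
                 tree_csv = tree_csv, plot_csv = plot_csv,
                 species = species,
                 refit_lumber_models = isTRUE(refit_lumber_models),
                 brt = brt, tc_grid = tc_grid, lr_grid = lr_grid,
                 band_candidates = band_candidates,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# predictor columns of a feature table: everything except identifiers,
# coordinates, the response, and generator ground truth
feature_predictors <- function(ft) {
  setdiff(names(ft), c("plot_id", "x", "y", "lvr", "lvr_true"))
}

#' Run the full LVR analysis pipeline
#'
#' Stages, in order: (1) simulate or load the sawing study and plot network;
#' (2) refit (or adopt) the lumber-value models and score every eligible
#' tree; (3) build the plot-level feature table; (4) fit (or grid-tune) the
#' boosted regression tree model of plot LVR and simplify it; (5) select the
#' hotspot distance band, compute Gi* and write the GeoJSON map. Each stage
#' writes its artifact under `config$out_dir`, and a manifest of seeds, row
#' counts and metrics is returned (and written as JSON). Any stage failure
#' aborts with an error naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, species = config$species,
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- stage 1: data ---------------------------------------------------------
  dat <- stage("simulate", {
    if (!is.null(config$tree_csv)) {
      list(trees = utils::read.csv(config$tree_csv),
           plots = utils::read.csv(config$plot_csv))
    } else {
      gen_tsp_database(config$tsp_spec)
    }
  })
  utils::write.csv(dat$trees, file.path(config$out_dir, "trees.csv"),
                   row.names = FALSE)
  utils::write.csv(dat$plots, file.path(config$out_dir, "plots.csv"),
                   row.names = FALSE)
  manifest$stages$simulate <- list(n_trees = nrow(dat$trees),
                                   n_plots = nrow(dat$plots))

  # -- stage 2: lumber-value models and tree scoring -------------------------
  models <- stage("score", {
    if (config$refit_lumber_models && !is.null(config$sawing_spec)) {
      saw <- gen_sawing_study(config$sawing_spec)
      utils::write.csv(saw, file.path(config$out_dir, "sawing_study.csv"),
                       row.names = FALSE)
      qf <- fit_qi_model(saw)
      vf <- fit_vsw_model(saw)
      list(qi = qf$params, vsw = vf$params,
           qi_adj_r2 = qf$adj_r_squared, vsw_adj_r2 = vf$adj_r_squared)
    } else {
      list(qi = qi_params(), vsw = vsw_params(),
           qi_adj_r2 = NA_real_, vsw_adj_r2 = NA_real_)
    }
  })
  scored <- stage("score", {
    elig <- filter_eligible(dat$trees, species = config$species)
    if (nrow(elig) == 0) stop("no eligible trees for ", config$species)
    score_trees(elig, models$qi, models$vsw,
                default_price_table(config$species))
  })
  utils::write.csv(scored, file.path(config$out_dir, "scored_trees.csv"),
                   row.names = FALSE)
  manifest$stages$score <- list(n_scored = nrow(scored),
                                qi_adj_r2 = models$qi_adj_r2,
                                vsw_adj_r2 = models$vsw_adj_r2,
                                mean_lvr = mean(scored$lvr))

  # -- stage 3: feature table ------------------------------------------------
  ft <- stage("features", {
    build_feature_table(dat$plots, dat$trees, models$qi, models$vsw,
                        species = config$species)[[config$species]]
  })
  utils::write.csv(ft, file.path(config$out_dir, "feature_table.csv"),
                   row.names = FALSE)
  manifest$stages$features <- list(n_plots = nrow(ft),
                                   n_predictors = length(feature_predictors(ft)))

  # -- stage 4: BRT ----------------------------------------------------------
  brt_out <- stage("fit", {
    preds <- feature_predictors(ft)
    sp <- split_train_validate(ft, config$brt$train_fraction,
                               seed = config$seed)
    if (!is.null(config$tc_grid) && !is.null(config$lr_grid)) {
      gs <- grid_search(sp$train, "lvr", preds, config$tc_grid,
                        config$lr_grid, config$brt)
      utils::write.csv(gs$leaderboard,
                       file.path(config$out_dir, "leaderboard.csv"),
                       row.names = FALSE)
      fit <- fit_brt(sp$train, "lvr", preds, gs$best$config,
                     validate = sp$validate)
    } else {
      fit <- fit_brt(sp$train, "lvr", preds, config$brt,
                     validate = sp$validate)
    }
    simple <- simplify_model(fit)
    list(fit = fit, simple = simple, split = sp)
  })
  infl <- sort(brt_out$fit$influence, decreasing = TRUE)
  utils::write.csv(data.frame(predictor = names(infl), influence = infl),
                   file.path(config$out_dir, "influence.csv"),
                   row.names = FALSE)
  manifest$stages$fit <- list(
    n_trees = brt_out$fit$n_trees,
    tc = brt_out$fit$config$tree_complexity,
    lr = brt_out$fit$config$learning_rate,
    d_squared = brt_out$fit$d_squared, rmse = brt_out$fit$rmse,
    retained = brt_out$simple$retained,
    top_influence = names(infl)[1:min(3, length(infl))])

  # -- stage 5: hotspots -----------------------------------------------------
  hs <- stage("hotspots", {
    hotspot_analysis(ft, "lvr", config$band_candidates)
  })
  if (hs$detected) {
    utils::write.csv(hs$results,
                     file.path(config$out_dir, "hotspots.csv"),
                     row.names = FALSE)
    stage("hotspots", write_hotspot_map(
      hs$results, ft[, c("plot_id", "x", "y")],
      file.path(config$out_dir, "hotspots.geojson")))
    counts <- table(hs$results$category)
    manifest$stages$hotspots <- list(band = hs$band$band,
                                     detected = TRUE,
                                     categories = as.list(counts))
  } else {
    manifest$stages$hotspots <- list(band = NA, detected = FALSE)
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(manifest)
}
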