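#!/usr/bin/env Rscript
# Stage 4 — boosted regression tree models of plot LVR.
#
# 70/30 train/validation split, then a 5 x 7 grid over tree complexity
# {1, 2, 5, 7, 10} and learning rate {0.1 ... 0.0001} (35 candidate models,
# bag fraction 0.5), ranking by cross-validated predictive deviance with a
# minimum-ensemble-size constraint. The winning configuration is refitted,
# summarised by validation D-squared and RMSE, relative influences and
# partial dependence, and simplified to its informative predictors.
# Ensemble-size limits are scaled to the 2000-plot study (see the methods
# vignette).

library(lvrscape)

seed <- 20260921L
out <- "results"

for (sp_name in c("yellow_birch", "sugar_maple")) {
  ft <- read.csv(file.path(out, paste0("features_", sp_name, ".csv")),
                 stringsAsFactors = TRUE)
  preds <- setdiff(names(ft), c("plot_id", "x", "y", "lvr", "lvr_true"))
  sp <- split_train_validate(ft, 0.7, seed = seed)
  cfg <- brt_config(min_trees = 20, max_trees = 60, cv_folds = 3,
                    seed = seed)
  gs <- grid_search(sp$train, "lvr", preds, config = cfg)
  write.csv(gs$leaderboard,
            file.path(out, paste0("brt_leaderboard_", sp_name, ".csv")),
            row.names = FALSE)
  best_cfg <- gs$best$config
  best_cfg$min_trees <- 50L
  best_cfg$max_trees <- 400L
  fit <- fit_brt(sp$train, "lvr", preds, best_cfg, validate = sp$validate)
  message(sprintf("%s: best tc %d lr %g; %d trees; validation D2 %.2f RMSE %.2f",
                  sp_name, fit$config$tree_complexity,
                  fit$config$learning_rate, fit$n_trees, fit$d_squared,
                  fit$rmse))
  infl <- sort(fit$influence, decreasing = TRUE)
  write.csv(data.frame(predictor = names(infl), influence = infl),
            file.path(out, paste0("brt_influence_", sp_name, ".csv")),
            row.names = FALSE)
  message("  top influences: ",
          paste(sprintf("%s %.1f%%", names(infl)[1:5], infl[1:5]),
                collapse = ", "))

  simple <- simplify_model(fit)
  message("  retained after simplification: ",
          paste(simple$retained, collapse = ", "))
  pd <- do.call(rbind, lapply(simple$retained, function(p) {
    cbind(predictor = p, partial_dependence(fit, p))
  }))
  write.csv(pd, file.path(out, paste0("brt_partial_dependence_", sp_name,
                                      ".csv")), row.names = FALSE)

  # validation predictions drive the hotspot stage
  ft$lvr_pred <- predict(fit, ft)
  write.csv(ft[, c("plot_id", "x", "y", "lvr", "lvr_pred")],
            file.path(out, paste0("brt_predictions_", sp_name, ".csv")),
            row.names = FALSE)
}
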