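#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Two datasets stand in for the confidential originals: (a) a 96-tree sawing
# study drawn from the recalibrated quality-index and sawn-wood-yield models
# plus observation noise, and (b) a 2000-plot temporary-sample-plot network
# on a 20 x 20 km projected extent, with three informative stand covariates
# (structural diversity +, basal area +, merchantable stem count -), one
# planted high-LVR cluster (radius 1.5 km, +30 $US/m^3 ~ 3.75 residual sd),
# and a full complement of uninformative stand/climate/soil covariates.

library(lvrscape)

seed <- 20260921L
out <- "results"
dir.create(out, showWarnings = FALSE)

saw_spec <- sawing_study_spec(seed = seed)
sawing <- gen_sawing_study(saw_spec)
write.csv(sawing, file.path(out, "sawing_study.csv"), row.names = FALSE)
message(sprintf("sawing study: %d trees, Vg %.2f-%.2f m3, mean QI %.2f",
                nrow(sawing), min(sawing$vg), max(sawing$vg),
                mean(sawing$qi)))

tsp_spec <- tsp_sim_spec(
  n_plots = 2000,
  cluster_centres = list(list(x = 5000, y = 5000, radius = 1500,
                              effect = 30)),
  seed = seed)
dat <- gen_tsp_database(tsp_spec)
write.csv(dat$plots, file.path(out, "plots.csv"), row.names = FALSE)
write.csv(dat$trees, file.path(out, "trees.csv"), row.names = FALSE)
message(sprintf("plot network: %d plots, %d trees (%.1f per plot)",
                nrow(dat$plots), nrow(dat$trees),
                nrow(dat$trees) / nrow(dat$plots)))
message(sprintf("latent LVR: mean %.1f, sd %.1f $US/m3",
                mean(dat$plots$lvr_true), sd(dat$plots$lvr_true)))
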