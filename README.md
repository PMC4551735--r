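# lvrscape

Landscape-scale analysis of lumber value recovery (LVR) in northern
hardwoods — yellow birch (*Betula alleghaniensis*) and sugar maple (*Acer
saccharum*).

LVR is the summed market value of the boards contained in a unit volume of
round wood ($US/m³). It is a practical indicator of timber quality: stumpage
is priced per roundwood volume, and unlike whole-tree board value, LVR is
only weakly tied to tree size, so it can be compared across sites. This
package is for forest biometricians and analysts who want to (1) score
individual hardwood trees for lumber value from per-grade log volumes,
(2) link plot-level LVR to stand, climate and soil-acidity descriptors with
boosted regression trees (BRT), and (3) locate statistically significant
regional clusters of high and low timber quality.

## The models at the core

Per tree, the scoring chain is

    LV  = QI · P · Vsw                    lumber value, $US
    QI  = Σ_{i: V_Fi > 0} (β_i + β₁ V_Fi² / V_g)   quality index
    Vsw = max(0, γ₀ + γ₁ V_g)             sawn-wood volume, m³
    LVR = LV / V_roundwood                $US/m³

with log grades F1–F4 (descending quality; F4 = short logs), gross volume
V_g, reference 1C board price P, and recalibrated defaults
β = (0.64, 1.09, 0.60, 0.49, 0.48), γ = (−0.01, 0.58). A grade's term enters
only when its volume is positive — the reading under which the four grade
intercepts are identifiable — and `fit_qi_model()` / `fit_vsw_model()`
re-estimate the coefficients from any sawing-study table.

Plot LVR (total LV over total roundwood volume of eligible trees, DBH
strictly > 23 cm) is modelled from stand descriptors — including exponential
Shannon species and structural diversity indices and critical acid-load
variables — by stochastic gradient boosting (bag fraction 0.5, 5 × 7 grid
over tree complexity {1,2,5,7,10} and learning rate 0.1…0.0001, ranked by
cross-validated deviance). Spatial clusters are detected with binary fixed
distance-band weights: the band is chosen by Global Moran's I (significant
at 1%, no isolated plots, z-maximising), local scores are self-inclusive
Getis-Ord Gi*, and plots are classified very_low / low / mean / high /
very_high at the two-sided 2.576 / 1.645 thresholds.

No provincial inventory data are distributed; synthetic generators with
known ground truth (`gen_sawing_study()`, `gen_tsp_database()`) stand in
for them and drive all tests.

## Worked example

```r
library(lvrscape)

# score a hand-specified tree: one F1 log of 0.5 m3 in a 0.5 m3 stem
tree <- data.frame(vf1 = 0.5, vf2 = 0, vf3 = 0, vf4 = 0,
                   vg = 0.5, roundwood_m3 = 0.6)
pt <- price_table("yellow_birch",
                  c(FAS = 181, "1C" = 100, "2C" = 70, "3C" = 25))
score_trees(tree, prices = pt)[, c("qi", "vsw", "lv", "lvr")]
#>      qi  vsw    lv  lvr
#> 1 1.185 0.28 33.18 55.3
```

QI is 0.64 + 1.09·0.5²/0.5 = 1.185; the 0.5 m³ stem saws to
−0.01 + 0.58·0.5 = 0.28 m³ of boards; at P = 100 $US/m³ the lumber value is
1.185·100·0.28 = 33.18 $US, i.e. 55.3 $US per m³ of round wood.

The full pipeline on a synthetic landscape:

```r
cfg <- pipeline_config(
  tsp_spec = tsp_sim_spec(
    n_plots = 2000,
    cluster_centres = list(list(x = 5000, y = 5000, radius = 1500,
                                effect = 30)),
    seed = 20260921),
  out_dir = "results/demo", seed = 20260921)
man <- run_pipeline(cfg)
```

The numbered scripts under `analysis/` run the same stages with narrative
output. On the shipped configuration they print, among other things:

```
recalibrated coefficients (estimate / SE / reference):
  beta0  0.726 0.080  0.64     gamma0 -0.0073 0.0139  -0.01
  beta1  1.127 0.114  1.09     gamma1  0.5768 0.0106   0.58
adjusted R2: QI 0.47, Vsw 0.969
yellow_birch: 3697 eligible trees, mean LVR 110.4 $US/m3 (sd 15.7)
yellow_birch: best tc 1 lr 0.1; validation D2 0.41 RMSE 10.69
  top influences: struct_div_gen 38.5%, stems_ha 30.9%, basal_area 25.1%, ...
  retained after simplification: basal_area, stems_ha, struct_div_gen
yellow_birch_lvr: band 2000 m (Moran z 7.4)
 very_low  low  mean  high  very_high
        9   86  1472    56         69
```

That is: the sawing-study refit recovers the recalibrated coefficients
within their standard errors; the BRT ranks exactly the three planted
covariates on top and simplification discards every noise predictor; and
the hotspot stage selects a 2 km band and flags the planted high-LVR
cluster (the `high`/`very_high` plots) against the mean background.

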