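---
title: "Modelling landscape-scale lumber value recovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling landscape-scale lumber value recovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvrscape)
```

## The problem

Lumber value recovery (LVR) is the summed market value of the boards that can
be sawn from a unit volume of round wood ($US/m³). Because stumpage is also
priced per unit roundwood volume, LVR is a tangible indicator of timber
quality for hardwood sawlogs, and — unlike whole-tree board value — it is
only weakly tied to tree size, which makes it comparable across sites. This
package implements a complete pipeline for studying site-to-site variation in
LVR of yellow birch (*Betula alleghaniensis*) and sugar maple (*Acer
saccharum*): a recalibrated lumber-value scoring model applied tree by tree,
aggregation to inventory plots with stand-level predictors, boosted
regression tree (BRT) models of plot LVR, and a fixed distance-band hotspot
analysis of the resulting spatial field.

Provincial inventory databases of the scale this method targets are not
public, so the package ships synthetic-data generators with known ground
truth; every stage is exercised and tested against them.

## The lumber-value scoring chain

A tree's lumber value is

$$LV = QI \cdot P \cdot V_{sw},$$

where $P$ is the market price of the reference board class (NHLA 1 Common,
$US/m³), $V_{sw}$ the sawn-wood volume (m³) and $QI$ a dimensionless quality
index. The classical $QI$ is the yield-weighted sum of relative board-class
prices, $QI = \sum_c Y_c\,RP_c$, with $RP_c$ the price of class $c$ divided
by the 1C price (`qi_from_yields()`, `compute_relative_prices()`). Because
board-class yields are rarely available outside mill studies, the
recalibrated model replaces them with per-grade log volumes, quantities a
grade-and-volume prediction system can supply for standing trees:

$$QI = \sum_{i \in \{F1..F4\},\; V_{Fi} > 0}
  \left( \beta_i + \beta_1 \frac{V_{Fi}^2}{V_g} \right),$$

where $V_{Fi}$ is the volume in log grade $Fi$ (F1–F3 in descending quality,
F4 short logs with small-end diameter 16–20 cm), $V_g$ the gross volume, and
the default coefficients are the sawing-study estimates
$\beta_{F1..F4} = (0.64, 0.60, 0.49, 0.48)$ with common slope
$\beta_1 = 1.09$. Sawn-wood volume is linear in gross volume,
$V_{sw} = \gamma_0 + \gamma_1 V_g$ with defaults $(-0.01, 0.58)$, clamped at
zero since the negative intercept would otherwise predict negative board
volume for very small stems. LVR is $LV$ divided by the tree's roundwood
volume (`score_trees()` chains the four steps).

Three structural choices deserve comment, as the model statement alone does
not force them:

* **Conditional term inclusion.** A grade's term $(\beta_i + \beta_1
  V_{Fi}^2/V_g)$ enters only when $V_{Fi} > 0$. If all four intercepts were
  always present only their sum would be estimable; conditional inclusion is
  the only reading under which four distinct intercepts are identifiable,
  and it is how `fit_qi_model()` builds its design (grade-presence
  indicators plus one pooled $\sum_i \mathbf{1}\{V_{Fi}>0\} V_{Fi}^2/V_g$
  regressor). A dataset in which every tree carries all four grades is
  rejected with an explicit unidentifiability error.
* **Intercept–grade mapping.** $\beta_0 \to F1$, $\beta_2 \to F2$,
  $\beta_3 \to F3$, $\beta_4 \to F4$, in the order the model is written; the
  monotone decline of the defaults mirrors descending grade quality.
* **Per-tree application.** The model is fitted and applied at the tree
  level throughout (gross volume of the scored unit), and when both species
  are present the recalibration is pooled across species, matching how the
  coefficients were estimated.

Default price tables carry the 2008–2012 relative price structure
(yellow birch FAS/1C/2C/3C = 1.81/1.00/0.70/0.25; sugar maple
1.65/1.00/0.69/0.37) anchored at a 1C price of 140 $US/m³. The anchor is a
package choice, not an estimate: with the attainable $QI$ range of the
recalibrated model (roughly 0.5–2.3) and $V_{sw}/V_{roundwood} \approx 0.5$,
it places typical scored trees in the 85–160 $US/m³ band reported for the
two species at the provincial scale. All values are $US with no inflation
adjustment.

## Stand-level features

Plots enter the analysis when they hold at least one target-species tree
with DBH strictly greater than 23 cm — the lowest merchantable sawlog
diameter of the provincial grading system; `filter_eligible()` reads
"larger than 23 cm" strictly, so a 23.0 cm tree is excluded. Two diversity
indices use the exponential Shannon form $H'_{exp} = \exp(-\sum_i p_i \ln
p_i)$, an effective number of classes between 1 and $S$: species shares for
the species diversity index, and 2-cm DBH-class shares for the structural
index. The 2-cm width follows the provincial inventory convention (the
method description leaves it open), and both indices are computed over all
merchantable trees of the plot, not only the sawlog-eligible subset. Soil
acidity enters through the maximum critical sulfur load
$CL_{max} = BC_{dep} - Cl_{dep} + BC_w - BC_u - Alk_{le(crit)}$ (all in
eq ha⁻¹ yr⁻¹) and its exceedance $S_{dep} - CL_{max}$.

The plot-level response is aggregated from tree LVR as total lumber value
over total roundwood volume — the volume-weighted mean, which is the natural
plot-scale analogue of the per-tree ratio definition; an unweighted mean is
available (`aggregate_plot_lvr(..., method = "mean")`) since the original
aggregation rule is not documented. Categorical stand descriptors (age,
height, density, drainage classes, ecological type, surficial deposit) are
validated against declared vocabularies and unknown codes fail fast rather
than being pooled into an "other" level.

## Boosted regression trees

Plot LVR is modelled from stand, climate and acidity predictors with
stochastic gradient boosting under squared-error loss: 70/30
train/validation split, bag fraction 0.5 (each tree fits a random half of
the training data drawn without replacement), tree complexity $tc \in \{1,
2, 5, 7, 10\}$ and learning rate $lr$ from 0.1 down to 0.0001 — a 5 × 7 grid
of 35 candidate models ranked by cross-validated predictive deviance, with a
minimum ensemble-size constraint and ties broken toward the slower learning
rate (slow rates shrink each tree's contribution and give more reliable
estimates). Model quality is summarised by the proportion of deviance
explained ($D^2 = 1 - \sum(y-\hat y)^2 / \sum(y - \bar y)^2$) and RMSE on
the validation set.

The boosting backend is xgboost. Tree complexity maps to `max_depth`
(identical stumps at $tc = 1$; at larger $tc$ both formulations admit
$tc$-way interactions, though the per-tree split budget differs between a
depth-limited and a split-limited tree), the learning rate to `eta`, the bag
fraction to `subsample`, and the L2 penalty is disabled so each tree is a
plain least-squares fit. The base prediction is the training mean, so short
ensembles are centred correctly. Categorical predictors are integer-coded
for the design matrix (an ordinal approximation; partial dependence still
evaluates the original levels). Everything above the backend is implemented
in the package:

* **Ensemble size** is selected by k-fold cross-validation on the training
  set (10-fold by default), constrained to at least `min_trees`; the
  stopping rule for the original analysis is not documented, so both the
  fold count and the minimum are configuration.
* **Relative influence** sums each predictor's squared-error split gains
  over all trees and rescales to 100 (`relative_influence()`).
* **Partial dependence** is Friedman's definition: the average prediction
  over training rows with one predictor forced to each grid value.
* **Simplification** drops the lowest-influence predictor while the
  cross-validated deviance rises by less than one standard error of the
  current model's cv deviance (`simplify_model()`); the original
  "change of predictive deviance" threshold is likewise undocumented, so
  the 1-SE rule is this package's choice and is exposed as an argument.

## Hotspot analysis

Spatial structure is assessed on projected planar coordinates with binary
fixed distance-band weights, boundary inclusive ($w_{ij} = 1$ iff
$d_{ij} \le d$; the convention matches common GIS fixed-band semantics and
is documented because the method description is silent). The analysis band
is selected by Global Moran's I

$$I = \frac{n}{W} \frac{\sum_i \sum_j w_{ij} z_i z_j}{\sum_i z_i^2},
\qquad E[I] = \frac{-1}{n-1},$$

with z-scores under the randomization (permutation) variance: among
candidate bands where every plot has at least one neighbour and Moran's I is
significant at the 1% level ("99% likelihood of real clusters"), the
z-maximising band is chosen; if none qualifies the result is an explicit
"no clustering detected". Local clusters are then scored with the
self-inclusive Getis-Ord Gi* statistic and classified two-sidedly:
$|z| \ge 2.576$ → very high/low ($\alpha = 0.01$), $1.645 \le |z| < 2.576$ →
high/low ($\alpha = 0.1$), otherwise mean. p-values use the standard-normal
approximation by default, mirroring common GIS practice; Monte-Carlo
permutation p-values are available as an option. No multiple-testing
correction is applied across plots (the categorical α thresholds are the
interface); an FDR adjustment can be layered on the returned p-values by the
user. Results are written as RFC 7946 GeoJSON with a category colour table
for mapping.

A note on the Gi* null: the closed-form moments are derived under full
randomization of all $n$ values. A conditional permutation that holds the
focal value fixed targets a slightly different null (its mean is shifted by
the focal deviation) and disagrees with the closed form by $|\Delta z|
\approx 0.2$ on 25-point fields, while the matching unconditional oracle
agrees to $\approx 0.02$; the package's permutation option is conditional
(the usual local-statistic convention), and the test suite checks the closed
form against the unconditional oracle it actually corresponds to.

## What the synthetic data emulate — and what they do not

`gen_sawing_study()` emulates a 96-tree mill study: gross volumes uniform on
0.2–2.0 m³, one to three log grades per tree with 50–95% of gross volume
allocated across them, and observed QI and Vsw equal to the model truth plus
homoscedastic Gaussian noise (Vsw clamped at zero). The noise structure of
the original data is not documented; Gaussian homoscedastic noise is an
assumption. The default noise levels (QI sd 0.42, Vsw sd 0.05 m³) were set
once so that a refit at $n = 96$ reproduces the reported adjusted R² scale
of the recalibration (≈0.50 for QI, ≈0.97 for Vsw), making replicated
refits a meaningful parameter-recovery exercise.

`gen_tsp_database()` builds a plot network on a 20 × 20 km projected extent
(2000 plots by default; the real network is an order of magnitude larger
and province-wide). Each plot's latent mean LVR is additive — baseline 110
$US/m³, covariate effects, planted circular cluster effects — plus a
Gaussian residual of sd 8 $US/m³, values chosen to match the reported
provincial LVR dispersion (means ≈110–117, regional sd well below the
tree-level sd). The default informative covariates mirror the reported
directions of association: structural diversity (+6 $US/m³ per sd), basal
area (+5), merchantable stem count (−5); every other generated covariate is
pure noise. Trees per plot are truncated-Poisson (mean 5, at least one
sawlog-eligible tree, matching the plot-inclusion rule); tree grade volumes
are solved from the QI model so that volume-weighted scoring approximately
recovers the plot's latent LVR — higher-quality trees carry logs of more
(and better) grades.

Passing tests on these data therefore demonstrate: unbiased recovery of the
lumber-value coefficients under the stated noise; detection of planted
covariate effects by BRT influence ranking and simplification; and detection
of planted spatial clusters through band selection, Gi* and classification.
They do not demonstrate realistic allometry or grade composition (the grade
mechanism is an inversion of the scoring model, not a biological model),
spatially structured covariates (covariates are placed independently of
space, so BRT *predictions* carry no spatial clusters here — on real
inventory data they would), log-grade prediction for standing trees, or the
small-$D^2$, high-noise regime of the real provincial fit.

## Numerical and degenerate-input choices

* Scoring a tree with no graded volume, zero gross volume, or zero roundwood
  volume is an error, not a zero.
* `predict_vsw()` clamps at 0; `gen_sawing_study()` clamps observed Vsw at 0.
* Moran's I and Gi* refuse constant fields (zero variance); Gi* returns NA
  for a plot whose band contains only itself and flags it as an isolate.
* Band selection requires at least two candidates and reports per-candidate
  I, z, p and isolate counts so a "no clustering" outcome is auditable.
* Grid-search ties prefer the slower learning rate; leaderboard ranks are NA
  for candidates failing the minimum-trees constraint.
* All generators restore the caller's RNG state (`local_seed()`), so
  identical spec + seed gives byte-identical output regardless of ambient
  RNG use.

## Problem sizes used by the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run at the
package's chosen study sizes: 200 replicated 96-tree sawing studies for
coefficient recovery; a 2000-plot landscape with one planted hotspot
(radius 1.5 km, +30 $US/m³ ≈ 3.75 residual sd) for the end-to-end stages;
the full 5 × 7 tuning grid with reduced ensemble limits (20–60 trees,
3-fold cv) for the grid-cardinality demonstration, and a larger ensemble
(up to 300–400 trees) for the reported fits; 20 random 25-point fields with
999 permutations each for the spatial-statistic oracles. These sizes give
stable results at desk scale; they are deliberately far below the 22,579
plots of the real provincial analysis, whose headline $D^2$/RMSE values are
tied to that confidential database and are not reproduction targets here.

## Known limitations

* The integer coding of categorical predictors imposes an artificial
  ordering inside trees; with many-level factors a one-hot or native
  categorical-split encoding would be preferable.
* The QI model's conditional term structure makes predictions discontinuous
  as a grade volume crosses zero; that is inherent to the published model
  form.
* Gi* p-values are unadjusted for multiplicity across plots, by design.
* The synthetic landscape's additive latent structure cannot probe the
  interaction-driven regime that motivates large tree complexities; grid
  winners on it tend toward small $tc$.
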