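# erkhistory

Decoding the history of ERK kinase activity from fixed-cell
immunofluorescence.

## The problem

ERK/MAPK signaling in single cells is dynamic — pulses, sustained plateaus,
delayed onsets, abrupt inhibitor-driven shutdowns — and its target proteins
(ETGs: Fra-1, Egr-1, c-Fos, pc-Fos, c-Myc, c-Jun, pERK, pRb) integrate that
activity on very different timescales. A multiplexed immunofluorescence
snapshot of the panel therefore carries a compressed record of the activity
history that preceded fixation. `erkhistory` is an R package for researchers
who combine live-cell biosensor imaging with endpoint staining (or who have
only the stains) and want to ask, quantitatively, how much history the
stains encode and how to read it back out.

The package implements, end to end:

* **Biosensor calibration** — associated fraction
  `f_A = 1 − (I_CFP/I_YFP)/R_P`, the calibration line
  `f_A = K_AU + (K_AP − K_AU)·p` fit from phos-tag anchor points, and the
  activity transform `x = (f_A − K_AU)/(K_AP − f_A)` with its exact inverse;
  replicate batch correction of stains by affine alignment of
  matched-condition medians in log10 space.
* **Pulse featurization** — prominence-based peak detection with
  width-at-half-prominence durations, and nine dynamic features per cell
  (mean, max, summed/average duration, summed/average pulse height, mean
  absolute derivative, inter-pulse interval, spectral mean frequency), plus
  per-timepoint stain–activity correlation profiles.
* **Forward models** — endpoint stain levels predicted from the activity
  trace by time-series linear regression, featurized linear regression, and
  a small 1-D convolutional network (2 conv layers, 16 channels, kernel 16;
  dense 192/64/64), with integrated-gradients attribution of timepoint
  importance.
* **Reverse models** — cross-validated single-stain and multiple linear
  regression inferring each dynamic feature from the stain panel,
  incremental predictor addition, condition-average models, and
  condition-exclusion analysis.
* **History classification** — k-means prototypes of activity trajectories
  (k = 5), a correlation filter (r ≥ 0.7), an AdaBoost.M2 ensemble (500
  rounds of depth-2 trees) predicting the prototype from stains, hexagonal
  regional aggregation (50 µm), whole-image decision trees, and spatial
  overlay tables.
* **A delay-ODE gene model** — ERK → transcription factor → mRNA (delayed,
  with negative feedback) → protein → phospho-protein, integrated by
  fixed-step RK4 in compiled code; parameter surveys over hypothetical genes
  screen which parameterizations make an endpoint stain informative about
  each dynamic feature.
* **Statistics** — a variance-corrected t-test for cells nested in
  replicates (ANOVA-style two-level variance composition, Welch/Satterthwaite
  combination), Benjamini–Hochberg FDR control, and proximity-ordered
  spatial heatmap ordering (hierarchical clustering with optimal leaf
  ordering).
* **A synthetic-data generator** — plates of single-cell traces under
  EGF-dose / MEK-inhibitor treatment designs with cell-to-cell
  heterogeneity, spatially clustered late activity bursts, ODE-derived stain
  panels with multiplicative noise, replicate batch factors, and lossless
  ground truth.

## Worked example

```r
library(erkhistory)

# 1. simulate a plate: 5 treatment archetypes x 3 replicates, 40 cells/well
dataset <- simulate_plate(default_layout(n_cells = 40, replicates = 3),
                          seed = 42)
#> Synthetic ERK dataset: 600 cells, 15 wells, 3 replicates

# 2. batch-correct the stains and featurize the traces
stains   <- batch_correct(dataset$stains,
                          reference = dataset$truth$reference_replicate)$corrected
traces   <- qc_traces(dataset$traces)
features <- erk_features(traces)
features[1:3, c("cell_id", "mean", "sum_duration", "frequency")]
#> # A tibble: 3 × 4
#>   cell_id  mean sum_duration frequency
#>   <chr>   <dbl>        <dbl>     <dbl>
#> 1 c00001  0.538         93.6     0.198
#> 2 c00002  0.527         70.8     0.138
#> 3 c00003  0.462        174.      0.166

# 3. reverse inference: predict mean ERK activity from the stain panel
mlr <- fit_reverse_mlr(stains, features, "mean")
glance(mlr)
#> # A tibble: 1 × 6
#>   feature r_squared   rmse     n n_predictors best_fold
#>   <chr>       <dbl>  <dbl> <int>        <int>     <int>
#> 1 mean        0.869 0.0912   600            8         7

# 4. signaling-history classes: k-means prototypes + boosted classifier
proto <- cluster_prototypes(traces, k = 5, seed = 1)
keep  <- filter_prototype_members(proto, r_min = 0.7)
clf   <- fit_history_classifier(stains,
                                proto$labels[keep, c("cell_id", "class")],
                                n_rounds = 200, folds = 10, seed = 1)
glance(clf)
#> # A tibble: 1 × 5
#>   accuracy cv_accuracy n_classes n_test n_rounds
#>      <dbl>       <dbl>     <int>  <int>    <int>
#> 1    0.982       0.969         5     55      200

sort(predictor_importance(clf), decreasing = TRUE)[1:4]
#>     Fra1     Egr1     cMyc     cFos
#> 7111.416 2542.943 1255.512 1097.972
```

Reading the output: per-cell features summarize each trace (mean calibrated
activity ~0.5 under these treatments; summed pulse duration in minutes;
spectral mean frequency in cycles/hour). The multiple regression explains
87% of the cell-to-cell variance in mean activity from the eight stains
alone. The boosted classifier recovers the five signaling-history archetypes
from stains at 98% test accuracy on this synthetic plate (chance is 20%), and
the slow-integrating Fra-1-like stain dominates the predictor importances —
the qualitative structure the method is designed to expose. On real data,
noise and unmodeled biology lower all of these numbers; the vignette
(`vignettes/erk-history-methods.Rmd`) spells out what the generator does and
does not emulate.

Plot helpers: `plot_traces()`, `autoplot()` on prototypes and attribution
maps, `plot_timepoint_correlation()`, `plot_overlay()`.

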