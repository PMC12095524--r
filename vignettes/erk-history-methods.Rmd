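---
title: "Methods: decoding ERK signaling history from endpoint stains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding ERK signaling history from endpoint stains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erkhistory)
```

# The problem

ERK kinase activity in an individual cell is a time series: pulses, plateaus,
delayed onsets, abrupt shutdowns. Its downstream target proteins (ETGs —
Fra-1, Egr-1, c-Fos, c-Myc, pRb and others) accumulate and decay on their own
timescales, so a single fixed-cell immunofluorescence snapshot of the panel
carries a compressed record of the activity history that preceded it.
`erkhistory` implements the full analysis chain for interrogating that
record: biosensor calibration, pulse featurization, forward prediction of
stain levels from activity, reverse inference of dynamics from stains,
classification of signaling-history archetypes, and a mechanistic
delay-differential-equation model that bounds what any endpoint readout can
encode. A synthetic-data generator with known ground truth stands in for a
combined live-cell/cyclic-immunofluorescence experiment, so every claim the
package makes is testable end to end.

# Biosensor calibration

The FRET reporter is read out as the associated fraction
$f_A = 1 - (I_{CFP}/I_{YFP})/R_P$, where $R_P$ is the channel power ratio.
Phos-tag anchor conditions provide pairs (phosphorylated fraction $p$, mean
$f_A$), and the calibration line is fit by ordinary least squares in the
affine form

$$f_A = K_{AU} + (K_{AP} - K_{AU})\,p,$$

the unique line whose endpoints ($K_{AU}$ at $p=0$, $K_{AP}$ at $p=1$) are
consistent with the activity transform

$$x = \frac{f_A - K_{AU}}{K_{AP} - f_A}, \qquad
  f_A = \frac{K_{AU} + x\,K_{AP}}{1 + x},$$

which maps the associated fraction to the concentration ratio of active ERK
to its competing phosphatases. (A published shorthand of the calibration line
multiplies $p$ by $K_{AU} + K_{AP}$; that form contradicts the transform's
own endpoints, so the affine form is used and the discrepancy is documented
here rather than propagated.) Measured $f_A$ outside $[K_{AU}, K_{AP})$ is
produced by noise and would make the transform undefined or negative; such
values are clamped to $[K_{AU}, K_{AP} - \varepsilon]$ with
$\varepsilon = 10^{-6}$ of the calibration span and flagged per cell. The
accepted range is a configurable policy, not a fitted constant, because the
original filtering rule ("cells out of the expected range") is not defined
quantitatively anywhere we could anchor to.

Batch correction aligns each stain target across replicates in log10 space:
condition medians of a source replicate are regressed onto the reference
replicate's, and the fitted affine map is applied to all single-cell values
of the source replicate. The map is monotone, so within-replicate rank order
is preserved, and re-running the correction is idempotent. A target with no
usable spread across the matched conditions (an ERK-independent stain under
ERK-directed treatments) identifies only the offset; such targets fall back
to pure median alignment with a warning rather than an unstable slope.

# Pulse featurization

Peaks are interior strict local maxima with topographic prominence at least a
threshold; the default threshold is 10% of the dataset's activity
interquartile range, shared across cells so pulse counts are comparable.
Three definitional choices are deliberate and swappable:

* **Duration** is width at half prominence (linear interpolation of the
  crossings), the standard parameter-free choice.
* **Average derivative** is the mean *absolute* first difference per minute;
  a signed mean would cancel rise against fall and erase exactly the
  pulsatility this feature is meant to capture.
* **Frequency** is the power-weighted mean frequency of the one-sided
  periodogram of the mean-subtracted trace, in cycles/hour. The trace is
  Hann-tapered and the FFT zero-padded 8-fold: with a plain rectangular
  window the sidelobe energy biases the power-weighted mean upward by 5–6%
  for 3–6 hour periods, while the tapered estimate recovers pure sinusoids
  of 1–6 hour period to better than 0.3%.

Cells with fewer than two detected pulses receive the observation window as
their inter-pulse interval — a defined upper bound rather than a missing
value — and carry an `interval_imputed` flag, so downstream regressions keep
all cells, matching the all-cells fits the feature set is used for.

# The delay-ODE gene model

A hypothetical ERK target gene is simulated in four stages: ERK
phosphorylates a transcription factor; the phosphorylated factor drives
transcription with delay $\tau_m$ under negative feedback from total
protein (Hill half-max $K_D$, exponent $v$); mRNA is translated with delay
$\tau_p$; and ERK phosphorylates the protein product, shifting it into a
separately degraded pool. The phosphorylation flux $k_{pP}\,ERK(t)\,P(t)$
leaves the unphosphorylated pool and enters the phosphorylated pool — the
mass-conserving reading of the two rate equations, which as printed use
inconsistent symbols for the same flux. With all degradation off and
production off, $P + P^P$ is conserved to integrator tolerance (a regression
test).

Integration is fixed-step RK4 with `dt` = 1 minute by default; delayed
states are read from the stored solution grid with linear interpolation, the
pre-history equals the initial condition, and the initial condition is the
steady state under the trace's pre-stimulus activity. With feedback the
steady state solves a scalar fixed-point equation whose implied total
protein is decreasing in the assumed total, so bisection on
$[0, \text{implied}(0)]$ is exact; without feedback the closed form is used.
Halving `dt` changes endpoint readouts by well under 0.1%, and the
integrator agrees with an independent general-purpose DDE solver to three
decimals on a reference gene.

For gene surveys, six parameters are varied (the paper's supplementary
parameter table is not reproduced in the main text, so the ranges here are
declared defaults): four rates log-uniform over $[10^{-3}, 10^{-1}]$ per
minute — half-lives from ~7 minutes to ~11.5 hours, spanning the transition
from recent-activity trackers to whole-recording integrators — the feedback
half-max log-uniform over $[0.3, 30]$ around the typical steady protein
level, and the baseline expression fraction uniform on $[0, 1]$
(transcription is parameterized as $k_b = f_{base}\,k_{txn}$,
$k_m = (1-f_{base})\,k_{txn}$ with $k_{txn}$ fixed, so the sampled quantity
is directly the fractional expression at baseline). The endpoint readout is
total protein $P + P^P$ (a total-protein antibody analog); a switch selects
$P^P$ only (phospho-antibody analog). Because the ranges are declared rather
than fitted, published survey fractions are not treated as reproduction
targets; the structural findings — slow-degrading genes encode mean activity
best, and both positively and negatively regulated genes arise — are the
tested claims.

# Forward models

Three models predict an endpoint stain from a trace: least squares on all
timepoints (collinearity handled by the SVD pseudoinverse, i.e. the
minimum-norm solution), least squares on the nine features, and a small 1-D
convolutional network (two same-padding conv layers, 16 channels, kernel 16;
dense layers 192/64/64; rectifier activations; linear scalar output). The
network trains with Adam at learning rate $10^{-3}$ for 100 epochs, batch
size 256, and L2 penalty $10^{-3}$ added to weight gradients — the training
paragraph's value; the alternative $10^{-2}$ from the hyperparameter sweep
is one configuration flag away. Inputs are z-scored with the global mean and
SD of the trace matrix (per-dataset rather than per-cell normalization, so
amplitude information survives) and targets are z-scored. The 192-unit first
dense layer is kept at 192 regardless of input length; with same-padding
convolutions the flattened width is `16 * length`, so "match the input size"
cannot hold exactly at 190 timepoints and the stated width wins. Splits are
stratified by well and condition: per fold, 20% test, then 20% of the
remainder validation (16% of all cells), 64% train.

Timepoint attribution uses integrated gradients along the straight path from
a baseline (all-zeros standardized trace by default) with a midpoint Riemann
sum. For a linear model the attribution is exactly
$w \circ (x - \text{baseline})$ and completeness is machine-exact. For the
rectifier network the output is piecewise linear in the input, so the
quadrature carries $O(1/\text{steps})$ error concentrated at activation
kinks; at 128 steps the completeness residual is below 2% of the output
scale, and assertions on the network use that relative scale while the
analytic identities are asserted on the linear model.

Window truncation (`truncate_window`) keeps the trailing `n` samples; the
default of 150 samples (15 h) is one configuration point standing in for the
several inconsistent windows quoted in different places for the truncation
experiment.

# Reverse models

Reverse inference regresses each dynamic feature on the stain panel (log10
intensities, z-scored predictors; coefficients reported on both scales).
Cross-validation follows the stated selection rule: 10 folds, keep the fold
model with the lowest test RMSE, refit it on all cells, and report that
fit's $R^2$ — the averaged-coefficient alternative is deliberately not the
default, to match the published procedure. Incremental-predictor curves add
stains in order of single-predictor $R^2$; the cumulative in-sample $R^2$ is
non-decreasing and ends at the full multiple-regression value by nesting.
Condition-average models regress condition means on condition means; with
independent per-cell noise, averaging removes the noise floor, so the
condition-level $R^2$ bounds the single-cell $R^2$ from above — a property
the acceptance suite verifies feature by feature.

# History classification

Traces are clustered by k-means (k = 5, best of 5 restarts) on the raw
calibrated activity vectors — no per-cell normalization, because amplitude
differences are part of the history classes; a z-scoring switch exists.
Cells whose trace correlates with their class centroid below r = 0.7 are
excluded from classifier training (they still receive predictions at
annotation time). The classifier is an AdaBoost.M2 ensemble — the
pseudo-loss formulation with a weight per (example, wrong label) pair — over
depth-2 trees, 500 rounds; the weak-learner depth is unstated in the source
and declared here. Model selection again keeps the best test fold of 10.
Predictor importance sums the split improvement of each stain over all weak
learners (primary splits only, so an unused predictor scores exactly zero).

Spatial aggregation assigns cells to a pointy-top hexagonal lattice
(circumradius 50 µm, anchored at the field origin so region ids are
reproducible), averages member traces and stains per region, and repeats
clustering plus classification at region level; a whole-image model averages
per well and uses a single decision tree because a few dozen samples cannot
support an ensemble. Region means are computed after the correlation filter
is applied to nothing — i.e., regions aggregate all cells, and the filter
operates on the region-level prototypes — since the source does not state
the order; the chosen order is the one that keeps region composition
independent of the clustering.

# Statistics and spatial ordering

Group comparisons use a variance-corrected two-sample t-test for cells
nested in replicates, under the linear error model in which a cell's
deviation is the sum of a cell-level and an experiment-level error. The pure
experiment-level component is estimated ANOVA-style as
$\max(\mathrm{var}(\text{replicate means}) - \overline{s^2_{within}}/\bar n,\,0)$
— the variance of replicate means already contains the cell-level
contribution, and adding it again would double-count and make the test
conservative (measured type-I error 0.024 instead of the intended ~0.05
level). The group-mean variance is then
$(\text{between} + \overline{s^2_{within}}/\bar n)/R$ with $R-1$ degrees of
freedom per group, combined Welch-style with Satterthwaite degrees of
freedom. Monte-Carlo calibration with three replicates per group and a
replicate random effect gives a type-I rate of ≈0.035 at the 0.05 level,
the mild conservativeness inherent to Welch at three replicates. False
discovery control is the Benjamini–Hochberg step-up via `stats::p.adjust`;
an exhaustive step-up enumeration serves as the oracle in tests.

Spatial heatmap ordering clusters the pairwise Euclidean distances of
time-averaged cell coordinates (average linkage) and then optimizes the leaf
order by flipping branches, never splitting clusters. Up to 200 leaves the
exact dynamic program over subtree end-leaf pairs is used; beyond that a
greedy bottom-up flip pass, because the exact method is cubic in the leaf
count and impractical in R at thousands of cells — the declared threshold is
a speed/exactness trade, not a statistical one.

# The synthetic-data generator

The generator defines the study conditions every test runs under. A plate
layout assigns each well a treatment; the default five-archetype layout
mirrors the canonical history classes (EGF then MEK inhibitor at 12 h;
control; EGF in the final 3 h; EGF at 10 h; sustained EGF), three
replicates, one treatment per well — so classes are spatially coherent
across the field, as in the experiment it emulates. Traces are built from:

* baseline 0.15 with Ornstein–Uhlenbeck jitter (SD 0.02, relaxation 30 min)
  and a fully inhibited floor of 0.03;
* a media-change transient at $t = 0$ shared by every cell (amplitude 0.2
  decaying over 90 min): imaging begins shortly after a media change, which
  transiently activates the pathway; without this shared structure a
  "consistently low" class has nothing to correlate with its centroid and
  the r ≥ 0.7 filter would empty it, contrary to the retained low cluster
  in the experiments being emulated;
* a saturating dose response (half-max 1 ng/ml) with an initial transient
  (decay 90 min) and partial adaptation of the sustained component;
* a Poisson pulse train (rate up to 0.5/h at saturating dose) with per-cell
  lognormal heterogeneity in amplitude and rate;
* exponential shutdown to the floor within ~6 min of MEK inhibition;
* for spatially clustered cells (clusters of 5–30 neighbors, 20% of cells),
  one synchronized burst in the final two hours.

None of the pulse-shape parameters are fitted values — the source describes
but does not parameterize its trace shapes — so they are declared defaults
chosen to look like published single-cell ERK recordings, set once and not
revisited. Stain panels are generated by running eight declared gene
parameterizations (slow integrators, intermediate responders, fast trackers,
and an ERK-independent control) through the delay-ODE model, multiplying the
endpoint by lognormal measurement noise (CV 0.1) and a per-replicate,
per-target batch factor (log10 SD 0.1, reference replicate fixed at 1).
Ground truth — archetype class, burst cluster, batch factors, noiseless
endpoints, gene parameters — is returned losslessly.

What the generator does **not** emulate: real segmentation/tracking errors,
non-lognormal stain artifacts, optical crosstalk between targets,
cell-cycle-coupled expression, spatial gradients in treatment, and any
nonlinearity between protein amount and antibody intensity. Tests passing on
this data therefore demonstrate that the algorithms are implemented
correctly and that the paper's structural claims hold under the stated
generative assumptions — not that the same accuracies would be reached on
the deposited experimental dataset, whose headline numbers are not
reproduction targets here.

# Problem sizes and determinism

The acceptance computations use sizes chosen to exercise each claim at
desk scale: 1,000 random traces against the brute-force peak oracle, 100
random parameter draws against the steady-state closed form, a 200-gene ×
1,000-cell survey, a 1,050-cell reverse-inference panel at 10% stain noise,
5,010 cells for the saturating-nonlinearity comparison (the convolutional
network trains for 30 epochs there — the margin over the time-series linear
model is ~0.3 $R^2$, so the full 100-epoch schedule adds nothing to the
comparison), a 3,000-cell classifier run with the full 500 boosting rounds,
and 10,000 Monte-Carlo null trials for test calibration. All randomness
flows through explicit seeds; the RNG state is saved and restored around
every seeded operation, so generator calls are reproducible and leave the
caller's RNG untouched.

# Known limitations

* The AdaBoost.M2 weak learners are depth-2 trees; very high-dimensional
  stain panels might favor deeper learners, which is a single argument.
* The CNN trains on CPU in compiled code; it is sized for 190-timepoint
  traces and a scalar target, not as a general deep-learning facility.
* The exact leaf-ordering DP is cubic; large wells fall back to the greedy
  branch-flip pass.
* Hexagon orientation and origin are fixed; regions are reproducible but not
  rotation-invariant.
* The delay integrator assumes delays of at least one step for full RK4
  accuracy; shorter delays are clamped to the most recent grid value.
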