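---
title: "Sitting-posture recognition with an improved self-organizing map: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sitting-posture recognition with an improved self-organizing map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomspr)
```

## The problem

A person sitting on a flexible resistive sensor mat produces a 32 × 32 map
of seat-contact pressure: two high-pressure ischial (sit-bone) peaks, two
broader thigh regions, and class-specific asymmetries. `isomspr` classifies
each frame into one of six common sitting postures — left/right cross-legs
(LC, RC), lean left/right (LL, LR), waist bow (WB), and standard sitting
(SS) — using an unsupervised self-organizing map (SOM) with six output
nodes on a hexagonal lattice, plus a sample-filtering retraining step that
sharpens the map.

The package contains the whole chain: the sensor transfer functions, a
synthetic frame generator (no hardware needed), per-frame PCA reduction,
the SOM and its improved variant, one-vs-rest evaluation metrics, and an
end-to-end reproducible experiment driver.

## Sensor model

Each of the 1024 induction points is a strain-gauge resistor read through a
voltage divider,

$$u_o = V_{ref}\,\frac{R_{ij}}{R_{ij} + R_{IM}},$$

with $V_{ref} = 5\,$V and $R_{IM} = 200\,$kΩ, and pressure follows the
measured calibration fit $p = 1690/R - 3.379$ (resistance in kΩ, adopted
for consistency with $R_{IM}$; the fit's units are not absolute, so all
pressures in the package are in "fit units"). Beyond the root of the fit
the raw value goes negative; frames are non-negative by contract, so the
fit output is clamped at zero. An acquisition threshold (`sensor_spec()`'s
`collection_threshold`) zeroes sub-threshold readings; its published value
is not stated, so the default is 0 — no silent data loss in tests.

## The synthetic generator

No pressure dataset is deposited with the method, so the generator is a
first-class module: each class template is a mixture of four 2-D Gaussian
load components (two ischial peaks, two thigh regions) whose centers,
spreads, and load shares encode the class geometry — SS symmetric; LL/LR
shifted 3 columns toward the named side with load share moved the same way;
LC/RC with the crossed leg's thigh nearly unloaded (share 0.04) and the
contralateral ischial peak raised; WB shifted 4 rows forward with 20 %
tighter spreads. Per frame, the generator jitters body placement
(sd 0.6 cells), component centers (sd 0.3 cells), load shares and spreads
(log-normal, sd 0.08 / 0.05), adds Gaussian sensor noise (sd 2 % of the
clean peak), clamps, thresholds, and rescales so total load is exactly
proportional to subject weight (drawn uniformly from 45–80 kg, the range
of the original study population; 10 fit-units per kg). These values were
fixed once as a plausible low-noise emulation of the published example
distributions and are all configurable via `gen_noise()`.

What the generator does **not** emulate: inter-subject anatomy beyond a
weight scale, temporal correlation between frames of one sitting bout,
sensor cross-talk, drift, or saturation. Passing tests on synthetic data
therefore demonstrate the pipeline's mechanics and relative orderings, not
field accuracy on human data.

## Dimensionality reduction

Each frame $P$ (32 × 32) is compressed by PCA on its column covariance
$R$ (sample covariance over the 32 rows, divisor 31): with $A$ the matrix
of the top-8 eigenvectors, $P_r = PA$ is 32 × 8 and flattens head-to-tail
(row-major) into a 256-element feature vector.

Two choices needed fixing where the procedure is underdetermined:

* **Sign/order convention.** Eigenvectors are sign-ambiguous; each column
  of $A$ is flipped so its largest-magnitude entry is positive, and
  eigenvalue ties keep the solver's order. Identical frames then always
  produce identical feature vectors.
* **Per-frame vs pooled basis.** Read literally, every frame gets its own
  $A$. That reading has an exact blind spot: for the column-reversal
  permutation $J$ (a left–right mirror), $P' = PJ$ gives $R' = JRJ$ and
  $A' = JA$ (the sign convention is mirror-stable), hence
  $P'A' = PJJA = PA$ — a frame and its mirror image produce *identical*
  features, so LC/RC and LL/LR collapse by construction. We verified this
  numerically: nearest-centroid accuracy is ~47 % on per-frame features
  (mirror pairs confused) versus >99 % on raw frames. `reduce_frame()`
  keeps the literal per-frame behavior (and a regression test documents the
  invariance), but the pipeline default is the **pooled** basis: one $A$
  fitted on the mean column covariance of the training frames
  (`pooled_basis()`), which breaks the mirror invariance and makes feature
  vectors comparable across frames. Degenerate covariances (rank < 8) are
  completed to an orthonormal basis by the symmetric eigensolver and
  flagged with a `degenerate` attribute.

## The self-organizing map

Six output nodes sit on a 2 × 3 hexagonal lattice (offset rows, unit
nearest-neighbor spacing; row 2 shifted +0.5 in x and $\sqrt3/2$ in y).
Samples and weights are L2-normalized. Per iteration $t$ (one sample
presentation), the best-matching unit (BMU) $c$ minimizes the Euclidean
distance to the input; every node $j$ in the winning neighborhood moves by
$\eta(t)\,h_{cj}(t)\,(x - w_j)$ with the Gaussian neighborhood
$h_{cj} = \exp(-D_{cj}^2 / 2\sigma(t)^2)$ and exponential schedules
$\eta(t) = \eta_0 e^{-t/\tau_\eta}$, $\sigma(t) = \sigma_0 e^{-t/\tau_\sigma}$.
Defaults are the published operating point: $\eta_0 = 0.6$,
$\tau_\eta = 1000$, $\sigma_0 = 10$, $\tau_\sigma = 2$, initial
neighborhood cap $N_c(0) = 3$, $r_{min} = 0.15$.

Decisions on points the procedure leaves open:

* **Stopping.** "Until the learning rate converges to 0" is implemented as
  `max_iters = 5000` updates or $\eta(t) <$ `eta_stop` $= 10^{-3}$,
  whichever first.
* **Neighborhood membership.** Node $j$ is in $N_c(t)$ when
  $D_{cj} \le \min(\sigma(t), N_c(0))$. Note the tension between the two
  time constants: with $\tau_\sigma = 2$ the cooperative phase lasts only
  a handful of iterations, after which only the winner updates, while
  $\tau_\eta = 1000$ keeps the learning rate high for thousands. Both are
  plain config fields; we keep the published values rather than "fixing"
  them.
* **Renormalization.** The update rule alone would let weights drift off
  the unit sphere while the distance computation assumes unit weights;
  updated weights are renormalized after every step so the model stays
  self-consistent.
* **Initialization.** Because the cooperative phase is so short, initial
  prototype placement effectively decides which node captures which class.
  Random unit-vector initialization left two classes sharing a node in
  roughly 4 of 10 seeds. The default is therefore a seeded farthest-point
  ("maximin") draw of training samples: a random start, then greedily the
  sample farthest from the chosen set. It is unsupervised, deterministic
  given the seed, and starts the prototypes mutually far apart; `"sample"`
  (uniform draw) and `"random"` remain available in `train_config()`.
* **Degenerate neighborhood width.** Once $\sigma(t)$ underflows to zero
  the winner's own $h$ is defined as 1 (its lattice distance is 0), so
  training never produces NaNs.
* **Labeling.** The map is unsupervised; nodes acquire class names by
  majority vote of the training samples they win, ties broken by the fixed
  class order LC < RC < LL < LR < WB < SS, and empty nodes inherit the
  nearest labeled node's class (weight-space distance).

## The improvement: differentiation filtering

After a first fit, distances between every training sample and the frozen
weights are recomputed. For sample $i$ with BMU $j$, the strongest rival
$k$ is the hex-adjacent node of $j$ with the smallest distance, and the
differentiation degree is

$$r_{jk} = \frac{|d_{ij} - d_{ik}|}{d_{ij} + d_{ik}} \in [0, 1],$$

zero when the sample is equidistant between the two nodes (defined as 0
when both distances vanish). Samples with $r_{jk} < r_{min}$ (default
0.15) are removed and the map is retrained from scratch on the kept subset
with fresh schedules under the same seed — one filter pass, no iteration.
Which node pair to score is not fully specified; we score BMU vs strongest
adjacent rival because that is the pair whose confusability matters for
the sample (scoring every adjacent pair would only lower $r$ further and
remove more). Two guards are ours: test data are never filtered, and a
class the filter would empty keeps its top-10 % (at least one)
highest-$r$ samples so every posture stays represented
(`strict = TRUE` disables this). Retraining with the same seed on a
filtered set re-runs the maximin draw on different data, so occasionally a
retrained map is worse on one seed; the median ordering over seeds is what
the method claims and what the tests check.

## Evaluation

Confusion matrices are 6 × 6, rows actual, columns predicted, fixed class
order. Per class, the one-vs-rest reduction gives TP/FP/FN/TN (always
summing to the grand total), precision TP/(TP+FP), recall TP/(TP+FN), and
one-vs-rest accuracy (TP+TN)/total; the headline accuracy is trace/total,
which on balanced classes equals macro recall exactly. Zero denominators
yield 0 with a `flagged` diagnostic instead of NaN. Printed percentages
use two decimals, rounded half-up, matching the published tables; the two
published confusion matrices ship as CSVs (`reported_confusion()`) and are
reproduced through this layer in the tests. The split is stratified:
`round(0.55 n_c)` per class to training, seeded shuffle.

## Problem sizes and determinism

The experiment driver and the acceptance script use 100 frames per class
(600 frames, 330 train / 270 test), 10 paired seeds for the SOM-vs-ISOM
comparison, and 10 % injected between-class midpoints as the ambiguity
stress; unit tests use 5–50 frames per class. These sizes give stable
medians while keeping a full run in the low minutes on one core. All
randomness flows through explicit seeds (`with_seed` restores global RNG
state), one top-level seed fans out to fixed per-stage offsets, and two
runs with the same config are byte-identical, including the JSON model
files (written with 17 significant digits for exact round-trips).

When the stratified split is infeasible (a class with fewer than two
frames), `run_experiment()` trains on the whole simulated set and
generates an independent test set of equal size under a derived seed, so
the smoke path stays honest about train/test separation.

## Known limitations

* The per-frame reduction's mirror invariance is inherent to column-space
  PCA of a single frame; the pooled default avoids it, but single-frame
  feature vectors computed in per-frame mode should never be compared
  across frames.
* Six nodes for six classes leaves no spare capacity: one bad prototype
  draw costs a whole class (visible as ~0.83 accuracy on rare seeds).
* The published schedule's topology preservation is weak (the cooperative
  phase is a few iterations), so "similar postures on adjacent nodes"
  holds as a tendency, not a guarantee.
* Synthetic results transfer to real seat-pressure data only to the extent
  the Gaussian-mixture templates match real load distributions.
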