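# isomspr

Sitting-posture recognition from seat-pressure maps with an improved
self-organizing map.

A flexible resistive mat on a chair seat yields 32 × 32 pressure frames:
two ischial (sit-bone) peaks, two thigh regions, and posture-specific
asymmetries. `isomspr` classifies each frame into one of six postures —
left/right cross-legs (LC, RC), lean left/right (LL, LR), waist bow (WB),
standard sitting (SS) — for ergonomics and sitting-habit monitoring.
Because no pressure dataset is publicly deposited for this task, the
package ships a seeded synthetic generator, so the whole pipeline runs
with no hardware and no downloads.

## Method

1. **Sensor model.** Per point, voltage divider
   `u_o = V_ref · R_ij / (R_ij + R_IM)` (`V_ref` = 5 V, `R_IM` = 200 kΩ)
   and calibration fit `p = 1690/R − 3.379` (R in kΩ), with an optional
   acquisition threshold.
2. **Reduction.** PCA on the frame's column covariance `R` (divisor 31);
   with `A` the top-8 eigenvectors, `P_r = P·A` is 32 × 8 and flattens
   row-major to a 256-vector. The pipeline default fits one basis on the
   training frames (pooled); the literal per-frame basis is available but
   is provably blind to left–right mirroring (see the methods vignette).
3. **SOM.** Six unit-norm 256-dim prototypes on a 2 × 3 hexagonal lattice;
   competitive learning with Gaussian neighborhood
   `h = exp(−D²/2σ(t)²)` and exponential decays
   `η(t) = 0.6·e^(−t/1000)`, `σ(t) = 10·e^(−t/2)`. Nodes are labeled by
   majority vote; prediction is the BMU's label.
4. **Improved SOM (ISOM).** After a first fit, each training sample gets a
   differentiation degree `r = |d_bmu − d_rival| / (d_bmu + d_rival)`
   against the strongest hex-adjacent rival of its BMU; samples with
   `r < 0.15` are dropped and the map is retrained, spreading the
   prototypes and removing boundary ambiguity.
5. **Evaluation.** 55/45 stratified split; 6 × 6 confusion matrices
   (rows actual), one-vs-rest precision/recall, macro averages, and
   trace/total accuracy, printed in the published table layout.

## Worked example

```r
library(isomspr)

cfg <- pipeline_config(n_per_class = 50, seed = 11)
res <- run_experiment(cfg)
print(res)
#> <spr_experiment> n_train = 168, n_test = 132
#>   SOM  accuracy: 99.24%
#>   ISOM accuracy: 99.24% (removed 0 ambiguous samples)
print(res$cm_isom)
#>           LC      RC     LL      LR      WB      SS      Total Recall
#> LC        22      0      0       0       0       0       22    100.00%
#> RC        0       22     0       0       0       0       22    100.00%
#> LL        0       1      21      0       0       0       22    95.45%
#> LR        0       0      0       22      0       0       22    100.00%
#> WB        0       0      0       0       22      0       22    100.00%
#> SS        0       0      0       0       0       22      22    100.00%
#> Total     22      23     21      22      22      22
#> Precision 100.00% 95.65% 100.00% 100.00% 100.00% 100.00%
```

300 synthetic frames (50 per class, subject weights 45–80 kg) are split
168/132; both maps recover the six posture clusters, and the held-out
confusion matrix shows a single LL frame predicted as RC (LL recall
95.45 %, RC precision 95.65 %). On clean low-noise data the filter finds
nothing to remove; inject ambiguous samples
(`inject_midpoints()`) to see it act.

The published worked-example confusion matrices are included and flow
through the same metrics layer:

```r
met <- confusion_metrics(reported_confusion("dataset1"))
print(met)
#> Per-class metrics (%):
#>  class precision recall
#>     LC     97.40 100.00
#>     RC     97.88 100.00
#>     LL     96.47  95.67
#>     LR     95.89  97.33
#>     WB     91.60  90.83
#>     SS     94.58  90.17
#> Macro precision: 95.64%  Macro recall: 95.67%
#> Overall accuracy: 95.67% (n = 3600)
```

A thin command-line front end (`inst/cli/isomspr.R`) exposes `simulate`,
`reduce`, `train`, `isom-train`, `predict`, `evaluate`, and
`run-experiment` verbs over the same functions.

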