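# octlongreg

Longitudinal analysis of peripapillary retinal nerve fiber layer thickness
(RNFLT) maps depends on the OCT scan pattern landing in the same place at
every visit. It never quite does: the operator re-centers the ring scan by
eye and the eye's orientation changes between sessions, so successive
thickness maps are misaligned by a small translation, rotation, and
magnification change. Sector features — the all-rings average, the
temporal/superior/nasal/inferior (TSNI) quadrant means, and the twelve
clock-hour means — are computed against fixed sector boundaries, so
misalignment moves anatomy across those boundaries and, when the
misalignment drifts over a study, fabricates longitudinal "change" in
sectors that sit on steep thickness gradients.

`octlongreg` is an R package for studying and correcting this effect. It
provides:

* **Two registration algorithms** for the en-face fundus images recorded
  with each session, both estimating a similarity transform
  (tx, ty, rotation θ, scale a):
  * **MI** — automatic mutual-information maximization,
    `MI(A,B) = H(A) + H(B) − H(A,B)` over 64-bin intensity histograms,
    searched exhaustively: a coarse joint grid (translation ±25 px step 5,
    rotation ±10° step 2°) followed by five sequential fine 1-D searches
    (scale 0.85–1.15 step 0.01, x/y-translation ±20 px step 1, rotation
    ±20° step 0.1°, scale again) centered on the running estimate.
  * **LPCC** — semi-automatic log-polar cross-correlation on segmented
    blood-vessel masks: rotation and scale become axis shifts in
    (angle, log-radius) coordinates, recovered by FFT cross-correlation
    (circular in angle, zero-padded in log-radius), with the origin of the
    log-polar map scanned over a bounded window to recover translation;
    two resolution levels (1/4-subsampled then full, origin windows ±10
    and ±4 px) with a 40 px global translation bound.
* **Registration quality metrics**: pixelwise vessel-overlap precision
  `TP/(TP+FP)` and recall `TP/(TP+FN)` inside the overlapped scanning
  region of each pair.
* **The 17 RNFLT sector features** computed on rasterized polar maps
  (100 rings × 100 a-scans, radii 0.75–1.5 mm), in the right-eye clock
  convention, before registration (full annulus per session) and after
  (common overlap of all co-aligned maps).
* **Longitudinal mixed-effects models** (REML via `nlme`): a paired
  comparison model `T = T_avg + b_i + γ·reg + ε` for precision/recall
  with vs. without registration, a trend model
  `RNFLT = (a₁ + β_i) + a₂·t + ξ` for feature change over days, and a
  residual-magnitude comparison between the two conditions.
* **A synthetic-data generator** — branched vessel trees, fundus-like
  images, double-hump thickness profiles, and longitudinal multi-subject
  series with known ground-truth misalignments (i.i.d. jitter plus slow
  drift) — so the whole pipeline can be exercised end to end with exact
  ground truth.

## Worked example

Simulate a jittered session pair, register it both ways, and score the
alignment:

```r
library(octlongreg)

vessels <- generate_vessel_tree(vessel_tree_spec(seed = 5), size = 256)
fundus  <- generate_fundus(vessels, background_seed = 6)
truth   <- similarity_transform(tx_px = 8, ty_px = -5,
                                rotation_deg = 4, scale = 1.03)
target_fundus  <- apply_transform(fundus, truth)
target_vessels <- apply_transform(vessels, truth)

res <- lpcc_register(vessels, target_vessels)
res$transform
#> <similarity_transform t=(-7.995, 4.290) px, rot=-4.000 deg, scale=0.9680>

precision_recall(vessels, target_vessels)$precision            # before
#> [1] 0.3626424
precision_recall(vessels,
                 apply_transform(target_vessels, res$transform))$precision
#> [1] 0.9438494
```

The estimated correction is (up to grid quantization) the inverse of the
applied misalignment — `compose_transforms(res$transform, truth)` here
leaves a residual of 0.07 px translation, 0° rotation, and 0.3% scale —
and vessel precision jumps from 0.36 to 0.94 after applying it.

The full experiment — simulate a 3-subject longitudinal series, register
every session, extract features before/after, and fit all models — is one
call:

```r
out <- run_experiment(experiment_config(output_dir = "run1", seed = 1))
```

which writes `evaluation.csv`, `features.csv`, `recovery.csv`,
`stats/{comparison,trends,residuals}.csv` and a `report.md` summarizing
registration recovery error, precision/recall by condition, and the
per-feature trend table. A thin command-line front end with the same
stages is installed at `inst/cli/octlongreg`
(`octlongreg synth|register|evaluate|features|stats|run`).

See `vignettes/registration-methods.Rmd` for the model details, parameter
choices, and the generator's assumptions.

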