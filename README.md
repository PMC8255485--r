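# usvscore

Occupancy-normalized scoring of rat ultrasonic vocalizations (USVs) in
X-maze preference sessions, for behavioral neuroscientists analyzing
manually annotated call labels together with video tracking.

Rats choosing between a social reward (a caged juvenile) and sucrose
solutions on the arms of an X-maze emit 50-kHz calls whose rate and
subtype mix depend on which reward they are near. Comparing those calls
across animals and zones requires normalizing two nuisances: animals
differ wildly in overall call output, and they spend different amounts
of time at each reward. This package implements the full pipeline:

* **Synchronization** — call labels (Avisoft-style exports) and
  position tracking (EthoVision-style exports) are fused on a 25 Hz
  raster. A frame (40 ms) carries a subtype when a call overlaps it by
  any positive amount; each frame takes the maze zone of the nearest
  tracking sample.
* **Scores** — per zone, call frames over occupancy seconds give the
  combined vocalization score over the 15-subtype universe (14 named
  50-kHz subtypes + Unclear, excluding 22-kHz calls),

      CVS_z = (call frames in z) / (occupancy seconds in z),

  per-subtype scores SVS, and the within-subject contrasts
  dCVS / dSVS = focal-zone minus other-zone score (higher sucrose vs
  lower in discrimination trials; juvenile vs sucrose in social
  trials). Behavioral preference is
  100 · t_focal / (t_focal + t_other) over reward-zone time, neutral
  platform excluded. Subtypes below 2% of pooled call frames are
  filtered from subtype-level statistics.
* **Statistics** — within-subject repeated-measures ANOVAs with
  Bonferroni post hocs and partial η², one-sample/paired t tests with
  Cohen's d, rank tests (Kruskal-Wallis, Mann-Whitney, Wilcoxon,
  Friedman) with exact small-sample nulls, Cohen's κ, and a
  random-intercept mixed model of dCVS/dSVS on sucrose concentration
  (lme4 REML; cluster-robust Wald CIs by default).
* **Synthetic cohorts** — a generator with known ground truth at every
  stage: semi-Markov zone dwell with condition-specific preferences,
  zone- and subtype-dependent Poisson call emission thinned to the
  one-hot constraint, and four-microphone amplitudes decaying with
  distance. Every downstream stage is validated against the generator's
  truth, including an exact count round trip through the file formats.

## Worked example

```r
library(usvscore)

# an 8-animal synthetic cohort: 2 SDT + 3 SSPT labeled conditions each
res <- run_pipeline(run_config("synthetic", seed = 20210621,
                               outdir = "results/run"))

# zone-level scores, one row per trial x zone
head(res$scored$zone_scores[, c("animal", "condition", "zone",
                                "occupancy_seconds", "call_frames",
                                "cvs", "role")], 4)
#>   animal condition         zone occupancy_seconds call_frames   cvs    role
#> 1      1      2v10 arm_E_reward               259          70 0.271   focal
#> 2      1      2v10 arm_W_reward               186          82 0.440   other
#> 3      1      2v10      neutral               155          18 0.116 neutral
#> 4      1      5v10 arm_E_reward               375          49 0.131   focal

# mixed model of dCVS on sucrose concentration
d <- cohort_delta_scores(res$scored, "SSPT")
fit_mixed_model(d$dcvs, "dcvs")
#> Random-intercept model (lmer_reml): slope = 0.0285, 95% CI [0.0173, 0.0398]
#>   t(7) = 6.01, p = 0.000539, marginal R2 = 0.492
```

The slope says how much the social-minus-sucrose call-rate difference
(frames/s) grows per percentage point of competing sucrose: animals
vocalize relatively more in the juvenile zone exactly when the sucrose
alternative is stronger. The generator plants this slope at 0.034; this
cohort estimates 0.0285 [0.0173, 0.0398], the CI excluding zero and
covering the truth. The `analysis/` scripts run the same stages as a
narrative workflow (simulate → score → stats → mixed model) and write
their tables under `results/`.

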