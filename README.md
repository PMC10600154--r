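# calfmove

Personality, plasticity and pen-mate conformity in dairy-calf movement,
from indoor positional tracking.

## The problem

Dairy calves are typically reared in small pair pens (1.5 × 3.5 m) and
later regrouped into larger social pens (6 × 10 m, up to 16 calves).
Ultra-wideband (UWB) collars log each calf's position at 1 Hz, and two
movement behaviours summarise each calf-day:

* **daily distance travelled** — the sum of distances between consecutive
  (smoothed) fixes over 24 h, a measure of *activity*;
* **residence time** — how long the calf stays within a 1-m circle centred
  on a fix, tolerating excursions shorter than 1 min, averaged over the
  day, a measure of *exploration*.

Three biological questions follow, each with a standard statistical tool:

1. **Personality** — do individuals differ consistently? The
   random-intercept linear mixed model

   `Y_ijk = (β0 + coh_k + ind_jk) + β1·day + β2·age + β3·housing + β4·health + e_ijk`

   yields the adjusted repeatability `R = V_ind0 / (V_ind0 + V_e0)`, the
   fraction of phenotypic variance (conditional on the fixed effects) due
   to individual identity.
2. **Personality-dependent plasticity** — do individuals differ in how
   they respond to the housing change? Adding a per-individual random
   slope on the housing contrast gives each calf an intercept
   (personality) and a slope (plasticity); their Pearson correlation is
   the personality–plasticity correlation.
3. **Social conformity and carry-over** — are pen-mates more alike than
   chance? The coefficient of variation of absolute pen-mate intercept
   differences is compared with its permutation distribution under random
   re-pairing (within cohort); a carry-over model adds own and pen-mate
   pair-housing intercepts as fixed effects to the group-housing model.

Because farm tracking data of this kind are rarely public, the package
ships a first-class synthetic-data generator with known ground truth at
two levels — daily metric panels drawn from the random-slope model
(including a conformity mechanism and cohort effects) and 1 Hz
rest/move-switching trajectories with UWB-scale noise — so every stage of
the pipeline is testable end to end. Sensor validation statistics (CEP,
the median-radius circular error probability, and DIST, mean distance to
ground truth) are included for static-tag tests.

## Worked example

```r
library(calfmove)

roster <- make_roster(n_cohorts = 6, calves_per_cohort = 16, seed = 42, n_days = 40)
cfg    <- metric_sim_config(seed = 42)   # distance-scaled defaults, R_true = 0.25
sim    <- simulate_metric_panel(roster, cfg)

fit <- fit_random_intercept(sim$panel)
adjusted_repeatability(fit, n_boot = 200, seed = 42)
#> <repeatability> R = 0.312 [0.250, 0.381] (200 bootstraps)

slope <- fit_random_slope(sim$panel)
personality_plasticity_correlation(slope)
#> <plasticity_correlation> r = 0.862 (p = 1.8e-29, n = 96); model parameter 0.669

pair_fit <- fit_random_intercept(sim$panel[sim$panel$housing == "pair", ])
ints <- setNames(pair_fit$individual_effects$intercept_dev,
                 pair_fit$individual_effects$calf_id)
permutation_test(ints, roster, B = 10000, seed = 42)
#> <penmate_permutation> observed CV = 0.7064, p = 0.7906 (lower tail, B = 10000)

coverage_report(85320, 9045)
#> <coverage_report> 9,045 of 85,320 calf-hours removed (10.6%); 0 out-of-pen fixes dropped
```

Reading the output: the generator drew individual intercepts worth 25% of
the (intercept + residual) variance, and the fitted `R` = 0.312 with a
bootstrap CI of [0.250, 0.381] recovers that scale (the default generator
also includes slope variance and conformity, which a pure
random-intercept fit absorbs partly into `V_ind0`). The intercept–slope
correlation of the predicted effects (0.862) is larger in magnitude than
the model-parameter correlation (0.669) because jointly shrunken BLUPs
are correlated beyond the generating ρ = 0.57 — both are reported for
that reason. The pen-mate p-value is the *lower-tail* proportion of
permutations whose null CV is at least the observed one; the convex-
blending conformity in the generator rescales all within-pair
differences equally and therefore cannot move this scale-free statistic
(see the methods vignette), so a non-significant p here is expected.
The housing fixed effect in this fit was 486.7 m/day (SE 17.2) against a
generating value of 496.2 m/day.

## Command line

```sh
Rscript inst/exec/calfmove run --config demo.json     # whole pipeline
Rscript inst/exec/calfmove simulate --config demo.json --out out/
Rscript inst/exec/calfmove analyze --metrics out/daily_metrics.csv \
    --model intercept --boot 1000 --seed 1 --out out/
Rscript inst/exec/calfmove penmate --effects out/individual_effects.csv \
    --roster out/roster --B 10000 --seed 1 --out out/
```

`run` writes every stage's artifact plus a `manifest.json` carrying the
seed, a config hash and per-stage row counts; re-running the same config
and seed reproduces every output byte for byte.

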