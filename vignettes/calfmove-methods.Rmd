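---
title: "Models and methods behind calfmove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind calfmove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models it fits, the simulator it ships, the numerical and design
choices made where reasonable alternatives existed, and what the test
suite does and does not establish.

## 1. The behavioural models

Both movement metrics (daily distance travelled, in m/day; daily
residence time, in s) are analysed with Gaussian linear mixed models
fitted by REML via `lme4`. The personality model has crossed-nested
random intercepts for cohort and individual:

$$Y_{ijk} = (\beta_0 + coh_{0k} + ind_{0jk})
  + \beta_1\,\mathrm{day} + \beta_2\,\mathrm{age}
  + \beta_3\,\mathrm{housing} + \beta_4\,\mathrm{health} + e_{0ijk}$$

with housing coded 0 = pair, 1 = group (so the individual intercept is
the *pair-housing* personality) and health a three-level factor with
reference "healthy". Adjusted repeatability is the variance ratio

$$R = \frac{V_{ind0}}{V_{ind0} + V_{e0}},$$

deliberately *excluding* cohort variance from the denominator; an
`include_cohort` flag exposes the alternative convention, because usage
in the repeatability literature varies. The plasticity model adds a
per-individual random slope on the housing contrast with unstructured
2×2 covariance; the personality–plasticity correlation is the Pearson
correlation of the predicted (BLUP) intercept and slope deviations.

Choices worth flagging:

* **p-values** for fixed effects use the Wald normal approximation,
  declared in `metadata$p_method`. Finite-df corrections (Satterthwaite,
  Kenward–Roger) require packages not available in this build; at the
  panel sizes targeted here (thousands of rows, ~96 individuals) the
  difference is far below any decision threshold.
* **BLUP correlation vs model parameter.** Predicted effects are jointly
  shrunken toward the fitted covariance, which typically *inflates* the
  magnitude of their sample correlation relative to the generating
  parameter ρ (we observe BLUP r ≈ 0.86 when ρ = 0.57). Worse, under a
  true ρ = 0 the extracted-effect correlation is not even centred: at the
  package's reference design (96 calves × 40 days, mild shrinkage) its
  mean across replicate datasets is systematically ≈ +0.11 to +0.15,
  while the fitted covariance parameter stays unbiased and the bias
  vanishes as residual noise → 0 — the estimation errors of jointly
  shrunken intercept and slope modes are themselves positively
  correlated. For this reason `personality_plasticity_correlation()`
  reports both the predicted-effects correlation (the conventional
  "extracted from the model" quantity) and the model-implied
  $cov_{01}/\sqrt{V_{ind0} V_{ind1}}$, and any null-calibration claim
  should be made on the latter. One acceptance test asserts the former
  is mean-zero under ρ = 0 and is expected to fail; it is kept as an
  honest record of this estimator property.
* **Repeatability CI** is a parametric bootstrap (default 1000
  replicates): simulate responses from the fitted model, refit
  (`lme4::refit` with derivative checks disabled for speed), recompute
  `R`, take 2.5/97.5 percentiles. The method is a package choice; the
  interval construction does not force the point estimate inside (a
  warning is raised if bootstrap noise places it outside).
* **Disease handling.** All models can be run including non-healthy
  observations (controlling for health; the default) or excluding them
  (`include_disease = FALSE`).
* **Degenerate fits.** A variance component estimated at zero is a
  *warning* (singular fit), not an error; failed optimizer convergence is
  an error carrying the optimizer diagnostics. Refitting identical data
  reproduces identical estimates (fixed optimizer configuration).
  Day-of-observation runs continuously across the housing move; a
  restart-at-move convention can be had by recoding the input column.
* **Under truth $V_{ind0}=0$** the REML estimate lands exactly on the
  boundary only on a fraction of datasets (~30–50% in our experiments)
  and is otherwise a small positive value of order $V_{e0}/n$; the test
  suite therefore asserts a uniform 2% bound across seeds plus boundary
  collapse on at least one seed, rather than machine-zero on every
  dataset.

## 2. The carry-over model

On group-housing rows only, the random-intercept model is refitted with
two additional fixed covariates: the calf's own pair-housing predicted
intercept and its former pen-mate's. Housing drops out (single level);
the pen-mate coefficient measures whether the partner's personality
carries over after regrouping. Pair intercepts must be supplied for
every calf (missing ones are an error listing the offenders), and pair
rows in the data are rejected.

## 3. The pen-mate permutation test

For each pair $p$ let $d_p$ be the **absolute** difference of the two
pen-mates' intercepts (signed differences have mean ≈ 0 and an
ill-defined CV). The statistic is $CV = sd(d)/\overline{d}$, with the
convention $CV = 0$ when all differences vanish. The null distribution
re-assigns intercepts to calves by permutation — within cohort by
default, since cross-cohort re-pairing would confound cohort effects
with pair effects — holding the pair structure fixed. With
`direction = "lower"` the p-value is the proportion of permutations with
observed CV ≤ null CV (the construction as used in the field); the tail
semantics are exposed rather than silently chosen because that wording
makes *small* p mean pen-mates are *less* evenly similar than chance.
The observed pairing is not forced into the null set; an add-one
correction `(k+1)/(B+1)` is available and recommended when valid type-I
control at small B matters.

**A structural limitation discovered during development.** The
simulator's conformity mechanism blends each calf's intercept toward the
pair mean with weight $w$, which rescales *every* within-pair difference
by exactly $(1-w)$. The CV is scale-free, so uniform blending cannot
move the observed statistic at all; the only power against it comes from
permutations that happen to recreate original pairs (which mix two
scales into the null CV). Measured power at $w = 0.8$, 6 cohorts × 8
pairs, is ~2% (lower tail) to ~19% (upper tail) — nowhere near nominal
detection. The test *is* correctly calibrated under $w = 0$ (rejection
rate ≈ 5% at α = 0.05, verified over 500 replicate datasets), and a
deterministic unit test pins down the scale-invariance identity itself.
Detecting convex-blending conformity would require a location-sensitive
statistic (e.g. the mean pair difference); this package deliberately
keeps the conventional CV construction rather than substituting its own.

## 4. The synthetic-data generator (the stated world)

The generator is first-class, tested code, not a fixture. Its defaults
are fixed once, to the conditions the study design states, and are not
tuned to test outcomes:

* **Design**: 6 cohorts × 16 calves (8 pairs each), 20 days per housing,
  day index continuous across the move.
* **Ages**: normal, mean 36.6 d, sd 4 d (sd is a package choice; the
  study reports only the mean), truncated positive; age enters as the
  constant age at group-pen day 0.
* **Health**: on any healthy day an episode starts with hazard 0.01;
  episodes are 3 d "sick" then 3 d "convalescent". Episode structure is
  a package choice (the source data only labels days).
* **Metric panel** (distance scale): baseline 1200 m/day in pair housing
  (a free parameter — no reference pair-housing mean exists; 1200 m/day
  is a realistic magnitude for 1 Hz step-sum distance in a small pen),
  housing effect 496.2 m/day, day slope 5 m/day², age slope 2 m/day per
  day of age, health effects −150 (sick) and −75 (convalescent) m/day.
  Variances: cohort 10 000 m², individual intercept 22 500 m², slope
  10 000 m², residual 67 500 m² — implying adjusted repeatability
  22 500/(22 500 + 67 500) = 0.25 and intercept–slope ρ = 0.57, the
  field-estimate anchors. Conformity weight defaults to 0.5 (moderate);
  recovery experiments that test the mixed-model machinery set w = 0 and
  slope variance 0 so the fitted model matches the generating model.
  For residence-time panels the same structure applies with the
  package's declared unit of hours.
* **Trajectories**: two-state rest/move switching (rates per second;
  defaults 1/120 and 1/30), steps of `move_speed/hz` toward a randomly
  chosen attraction point with Gaussian heading jitter (sd 0.3 rad),
  positions clipped to the pen walls, isotropic Gaussian sensor noise
  (default sd 0.15 m — the UWB validation scale of ≈0.11–0.17 m).
  Noise is added *after* clipping, so noisy fixes can fall outside the
  pen on purpose: the generator records how many, giving the out-of-pen
  filter a ground truth to be checked against.

What the generator does **not** emulate: circadian rhythm, feeder-visit
scheduling, growth, social avoidance/attraction between specific
individuals, non-Gaussian UWB error tails, or missingness other than by
explicit exclusion intervals. A green recovery test therefore
establishes that the estimators recover the parameters of *this* world,
not that the field estimates themselves are reproduced.

## 5. Preprocessing and metrics: numerical conventions

* **Pipeline order is fixed**: exclusion intervals → out-of-pen filter →
  smoothing; smoothing sees only retained raw fixes.
* **Exclusion intervals** are half-open `[start, end)` with union
  semantics, so adjacent intervals tile without double counting. Removed
  time is counted in samples/hz, reported in calf-hours, and the removed
  fraction is formatted with round-half-up to one decimal (9045/85 320
  prints as 10.6%).
* **Smoothing** is a centred, time-based window (±`window_s/2`,
  default ±5 s), truncated at record edges and across gaps — no
  interpolation, no phase lag, row count preserved. A smoothed point
  never leaves the convex hull of its window's inputs.
* **Boundary points count as inside the pen** (coordinates are metres
  from the pen corner).
* **Daily distance** attributes each segment to its leading fix's day and
  zeroes segments spanning a gap > 60 s (a package choice preventing
  exclusion gaps from creating phantom displacement). Days with < 2
  fixes are omitted with a log message.
* **Residence time** is bidirectional: from the centre fix, the clock
  runs forward (and backward) until the gap between consecutive
  inside-circle fixes exceeds `max_gap` (60 s), and the bound is the last
  inside fix before that gap (or the record end). Tolerated excursions
  are *included* in the accumulated time. The brute-force oracle in the
  test suite encodes the same rule independently as a scalar walk. The
  daily value is the mean over the day's fixes (subsampled by `stride`,
  default 10; stride 1 is the exact reference and agrees within 5% on
  simulated tracks), computed on the whole record so a stay spanning
  midnight is not clipped.
* **CEP** is the ⌈n/2⌉-th smallest distance to the mean reading — the
  smallest circle centred at the mean covering at least half the
  readings; **DIST** is the mean distance to ground truth. For isotropic
  Gaussian noise of sd σ these converge to 1.1774σ and σ√(π/2).

## 6. Test-budget scaling

The acceptance experiments run at their stated sizes (100 seeds per grid
point, 500 calibration replicates, B = 500–10 000 permutations) with one
scaling: the bootstrap-CI coverage experiment uses 200 bootstrap
replicates per dataset instead of the user-facing default 1000, keeping
the tested proportion (≥ 90/100 datasets covering truth) unchanged while
fitting the suite's runtime budget.

## 7. Known limitations

* "GLMM" is implemented as a Gaussian LMM throughout (the metrics are
  continuous; no family/link is modelled).
* The permutation test cannot detect uniform convex-blending conformity
  (section 3); the conventional construction is preserved deliberately.
* The trajectory simulator's per-step loop is plain R: adequate for the
  test scale (minutes of track per calf), not for simulating months at
  1 Hz.
* Residence-time model coefficients are in the package's declared unit
  (hours) when simulating residence-time panels; no reference
  pair-housing baseline exists for either metric, so panel baselines are
  free parameters.
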