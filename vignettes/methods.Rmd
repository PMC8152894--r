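---
title: "Models and methods behind ramplab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ramplab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

ramplab analyzes simultaneous single-unit recordings from the medial frontal
cortex (MFC) and dorsomedial striatum (DMS) while rodents perform
fixed-interval timing with one or two intervals. The task structure the
package assumes: a house light cues trial start; the first lever press after
the interval (3 s or 12 s) is rewarded; trials are separated by 6/8/10/12 s
intertrial intervals; one session per day, with a single-interval (FI12-only)
day followed by days on which FI3 and FI12 trials are randomly intermixed.
This vignette records the models, parameter choices and numerical
conventions, including the places where the design was genuinely open.

## Data model

A session (`fi_session`) is a trial table, a unit table with list-column
spike trains and waveforms, and (animal, day) metadata. All analysis
coordinates are seconds relative to cue onset; the session clock appears
only in raw storage. Serialization is one CSV per entity plus a JSON
manifest, with floats written in their shortest exact decimal form so that
`read_session(write_session(x))` is the identity bit for bit — important
because the test suite uses byte-identical re-serialization as its
determinism check. Rewards are modeled as the first press after interval
end, which also ends the trial span.

## Synthetic experiments

The generator exists so that every downstream stage has ground truth. Its
defaults describe the experiment the package targets: 7 animals, days 0–3
(day 0 FI12-only), intermixed trials on days 1–3, 8 units per area per
session.

**Behavior** is a two-state process: each trial has a latent start time
$s \sim \mathcal N(0.8\,T,\ (0.15 \cdot 0.8\,T)^2)$ truncated to $(0, T)$,
with lever presses at 0.05 Hz before $s$ and 1.0 Hz after, until the first
press after $T$ (rewarded). Both the mean and SD of $s$ scale with $T$, so
start-time variability is scalar (equal CV on FI3 and FI12) by
construction. The 0.8 fraction puts the mean FI12 start near 9.6 s, in the
range of typical fixed-interval response times; 0.15 is a conventional
timing CV. No published behavioral model exists for this task at the trial
level — this is the minimal structure the single-trial analysis assumes,
and the defaults are conventions, not fitted values.

**Spikes** come from an exact inhomogeneous-Poisson thinning sampler (no
time discretization, hence no bin-size artifacts), followed by a 2 ms dead
time as expected of a well-sorted unit. Intensities are
$\lambda(t) = \max(0,\ \text{baseline} + \text{class term})$ with baseline
5 Hz: ramping units add $\pm \beta t$ within the interval with
$\beta_{FI3} = 4\,\beta_{FI12}$ (the 12/3 interval ratio, the scaling a
drift-diffusion account of interval timing predicts) and
$\beta_{FI12} = 0.5$ Hz/s; interval-modulated units add a baseline-sized
offset on one randomly chosen interval type; response-locked units add a
Gaussian bump (SD 0.3 s, peak one baseline) around each press; untuned
units are homogeneous. Class fractions default to 0.4 ramping (half up,
half down), 0.25 interval-modulated, 0.1 response-locked, remainder
untuned, allocated deterministically so configured fractions are exact.

**Waveforms** are differences of two Gaussians. Broad templates
(MSN-like/pyramidal-like: half-peak width 0.30 ± 0.02 ms, peak-to-trough
ratio 1.6 ± 0.08) and narrow templates (interneuron-like: 0.12 ± 0.012 ms,
0.85 ± 0.07) are separated by >5 SDs in both features, so waveform
classification on generated populations is expected to be error-free;
additive noise is 2% of peak.

What the generator does **not** emulate: learning dynamics across days (no
day-dependent parameter schedule is applied by default), cue-onset
transients, bursting or non-Poisson interval statistics, electrode drift,
or correlated noise across units. Passing tests therefore demonstrate
correctness of the estimators under the stated model, not robustness to
every property of real recordings.

## Unit screening and classification

Units are included if their mean rate over the session exceeds 0.1 Hz and
at most 1% of interspike intervals fall below 2 ms. A strict zero-violation
rule was rejected: a "consistent" refractory period tolerates rare
coincidence violations, and the generator itself (Poisson with dead time)
produces none, so the 1% tolerance only matters for real data. The
MSN/interneuron boundary uses half-peak width ≥ 0.20 ms **and**
peak-to-trough ratio ≥ 1.2 (both configurable): the feature pair is
standard for striatal recordings but published cutoffs vary, so the values
sit in the gap between the two template classes and are surfaced in
`classifier_thresholds()`. Ratios use absolute amplitudes. MFC units are
labelled putative pyramidal throughout, cortical interneurons being assumed
removed at spike sorting. Half-peak width is measured between the two
half-maximum crossings around the positive peak with linear interpolation
between samples, so its resolution is finer than the 25 µs sampling step.

## PETHs, PCA and slopes

Per-trial firing rates are Gaussian kernel-density estimates (each kernel
integrates to one spike, giving Hz), evaluated exactly at 0.1 s bin centers
over $[0, T]$ and averaged over trials. Bandwidths are 0.2 s (FI3) and
0.5 s (FI12). Kernels are truncated at ±4 bandwidths; no edge reflection is
applied — mass falling outside the interval is simply not counted. Rows are
z-scored per unit; zero-variance rows cannot be z-scored and are dropped
with a warning naming the unit.

PCA treats units as observations and bins as variables, column-centered,
on the covariance (after row z-scoring, covariance and correlation PCA are
nearly equivalent; covariance was chosen). The default pools all areas and
days into one PCA so scores are comparable across groups; per-area PCA is a
matter of subsetting the input. Ramping strength is |PC1 score|, invariant
to the arbitrary sign of PC1 and to unit ordering.

Per-neuron slopes are identity-link least squares of trial-averaged binned
rate on bin time, with the regression t-test p-value; identity link keeps
the slope in Hz/s, directly comparable across intervals, and under the
generator's Poisson noise the averaged bin rates are homoskedastic under
the null, so the t-test is calibrated (verified at 1000 null units). A
log-link count-GLM alternative is available behind `method = "poisson"`.
A unit is "ramping" when the slope p-value is below 0.05 — the same α used
for interval modulation, since no separate criterion is standard.
Interval modulation is screened per unit by a Poisson GLM of per-trial
in-interval counts on interval type with log-duration exposure offset, so
the tested effect is a rate difference; at least 10 trials per type are
required, otherwise the unit's result is `NA`.

## Temporal decoding

The decoder predicts time within the trial from the ensemble rate vector.
Features are per-trial KDE rates (bandwidth 1.2 s — interpreted as seconds
of temporal smoothing; a rate-space reading of that constant was
considered and rejected because the quantity smoothed is a time series)
on 0.1 s bins over a window padded 6 s before the cue and 6 s after
interval end. Padded bins participate in training and as prediction
candidates, preventing edge bias, but are excluded from scoring.

The likelihood is per-unit, per-bin Poisson with mean = training-mean rate
× bin width (naive factorization across units), the same family used for
all firing-rate models; a Gaussian-KDE likelihood over training rates is
available as an alternative. Training rates are floored at 0.001 Hz to
keep log-likelihoods finite in silent bins. Under leave-one-out
cross-validation each trial is decoded from a model trained on the rest;
the maximum a posteriori bin under a uniform prior is the prediction, ties
breaking toward the earliest bin (so a totally uninformative ensemble
degenerates to the first padded bin and a defined R² of 0). R² is the
squared Pearson correlation of observed and predicted time pooled over
in-interval bins (an explained-variance form `1 - SS_res/SS_tot` is
available by flag). The null model circularly shifts each unit's rate
vector on each trial by an independent uniform offset — preserving rate
marginals and autocorrelation while destroying time locking; independent
bin permutation was implemented as an alternative reading but the circular
shift is the default because it is the stricter null.

One behavior worth knowing: in ensembles composed **only** of linear ramps,
the ensemble rate vector at early in-interval times equals its pre-cue
baseline, so early bins are genuinely confusable with padded bins. Median
absolute decoding error stays small (&lt;1 s), but the pooled Pearson R² is
sensitive to those pad-assigned outliers and can be modest even when
decoding is clearly better than the shuffled null. Mixed ensembles
(response-locked or interval-modulated units, cue transients) disambiguate
the pad and yield much higher R², as in the README example.

## Single-trial start times and the scalar property

Fixed-interval trials end at reward, so only the start transition of the
classic single-trial analysis exists. Over candidate change points
$s \in$ press times, the estimator maximizes
$s\,(r_{ov} - r_{pre}(s)) + (T - s)\,(r_{post}(s) - r_{ov})$, the press at
$s$ counting toward the post segment and ties breaking earliest. At least
2 presses are required; trials below that yield `NA` and are excluded from
CVs (matching the practice of dropping animals/conditions with too few
trials). The CV is the sample SD over the mean.

Two properties of this estimator matter for interpretation. It is
press-valued, so it cannot land before the first post-transition press:
with a 1.0 Hz post-start press rate its error has a one-sided floor of
order one inter-press interval (median ln 2 ≈ 0.7 s). And the segment
rates entering the index are estimated from the handful of presses in one
trial (~8 on FI12 at the default rates), so single-trial estimates are
noisy; recovery of planted transitions is therefore assessed at the
condition level, where the per-level median tracks the planted grid
monotonically with r > 0.9. Comparisons **between** conditions (FI3 vs
FI12, across days) are unaffected because the delay bias is shared.

## Statistical models

`model_spec()`/`fit_model()` encode the model families used throughout:
gaussian outcomes (response times, start times, CVs, |PC1 scores|,
|slopes|) with animal- or neuron-level random intercepts fit by
REML/lmerTest with Satterthwaite F tests; Poisson outcomes (binned firing
rates) fit by Laplace glmer with Wald chi-square per term. The
denominator-df convention of mixed-model F tests varies across software,
so outputs report statistic and p-value without asserting any particular
df accounting. Singular random-effects fits are flagged and refit with
fixed effects only, with a warning. Post hoc contrasts are estimated
marginal means with Tukey adjustment; for a two-level factor Tukey leaves
the p-value unchanged. The 2×2 chi-square is Pearson's without continuity
correction — the convention that reproduces the printed statistic from the
printed counts it is tested against. Cohen's d for paired samples is
mean(d)/SD(d), with a capped value flagged when the differences have zero
variance. A Bayes-factor for the scalar-CV null is out of scope: no prior
or formula is standard enough to pin down.

## Problem sizes and runtime

Test and acceptance simulations are sized to their purpose: 500
trials/interval for scalar-CV checks, 200 trials for slope and transition
recovery, 1000 null units for type-I calibration (binomial SE ≈ 0.007),
20 replicate 20-unit ensembles for the real-vs-shuffled decoding
comparison, and 7 × 400 observations for mixed-model recovery. These are
the sizes at which the tested tolerances are a few standard errors wide;
larger runs only slow the suite without changing what passes.

## Interfaces

The package is function-first: `run_pipeline(pipeline_config(...))`
orchestrates simulate → classify → behavior → ramping → decode → stats
with per-(stage, animal, day) seed substreams derived from one master
seed, writes per-stage CSVs, a JSON summary and a JSON-lines log, and is
byte-deterministic given (config, seed). `make_fixtures()` writes a
miniature two-animal dataset exercising every trial and unit class. R
functions, the report directory and this vignette are the intended user
surface; no shell binary is shipped.
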