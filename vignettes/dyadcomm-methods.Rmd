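---
title: "Models and methods behind dyadcomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dyadcomm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadcomm)
```

`dyadcomm` analyses nonverbal communication between a patient and a
clinician during pain treatment. Its inputs are framewise facial
action-unit (AU) time series for both members of a dyad (20 channels at
20 frames/s), block annotations of the experimental protocol, behavioural
questionnaire scores, and trial-wise brain parcel activity. Four analysis
stages build on each other:

1. a gradient-boosted classifier that discriminates moderately painful
   from innocuous pressure from the patient's AU frames and ranks the AUs
   by SHAP importance;
2. an echo-state-network (ESN) estimator of nonlinear Granger causality
   (GC) between every patient AU and every clinician AU, in both
   directions, over the 12 anticipation blocks of a session;
3. group-level inference on each of the 400 directed AU-to-AU links per
   direction against an empirical pseudo-dyad null, with
   Benjamini-Hochberg FDR control;
4. a trial-wise (beta-series) cross-brain concordance regression linking
   the facial-causality score to brain coupling and to behavioural
   measures of therapeutic alliance and negative-affect expressivity.

Because raw video and fMRI recordings of this kind are not publicly
distributable, the package ships a synthetic-data module that generates
dyadic AU streams, pain sessions, and dyadic brain/behaviour data with
known ground truth. All tests and the acceptance analyses run against
this generator.

## Echo-state Granger causality

For a source series $x$ and target series $y$, Granger causality asks
whether the past of $x$ improves prediction of $y$ beyond $y$'s own past.
The package quantifies this nonlinearly with an ESN: a fixed random
recurrent network

$$ s_t = (1-\alpha)\, s_{t-1} + \alpha \tanh(W s_{t-1} + W_{in} u_t + b) $$

with leak rate $\alpha$, recurrent weights $W$ rescaled to spectral
radius $\rho < 1$ (the echo-state property: input-driven states have
fading memory), uniform input weights $W_{in}$, and a per-unit constant
bias $b$. Only a linear readout predicting $y_{t+1}$ from $s_t$ is
trained, by ridge regression, so the trainable parameter count is
minimal and overfitting is limited by construction. The GC strength is

$$ F_{x \to y} = \ln \frac{\mathrm{MSE}_{restricted}}{\mathrm{MSE}_{full}}, $$

where the restricted model drives the reservoir with $y$ alone and the
full model with $(y, x)$ jointly. Both MSEs are *held-out* errors pooled
by leave-one-block-out cross-validation over the 12 anticipation blocks;
in-sample residuals would reward readout overfitting. Estimates are
averaged over `n_reservoirs` independent reservoir realisations
(recurrent weights shared between restricted and full models of a
realisation, input weights drawn independently per input
dimensionality). Negative estimates are retained: clipping at zero would
bias the null distribution that the rank-based inference depends on.

### Why the bias term matters

$\tanh$ is odd, so a bias-free reservoir driven by a single input
produces state trajectories that negate when the input negates; a linear
readout of such states is an odd function of the input history and
cannot represent even components such as a squared lagged source. With a
per-unit bias (default scale 0.5) the symmetry is broken and the
estimator detects, for example, $y_t = c\,(x_{t-1}^2 - 1) + \epsilon$ —
a coupling with exactly zero linear cross-correlation that the classical
log-variance-ratio GC (provided as `linear_gc()`, the validation oracle)
cannot see. The cost of the bias is that reservoir states are no longer
zero under zero input; `esn_states()` with `input_bias = 0` recovers the
textbook bias-free behaviour.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_units` | 100 | reservoir size; larger = richer nonlinear features |
| `spectral_radius` | 0.9 | memory length of the reservoir (< 1) |
| `input_scale` | 1.0 | input weight scale (inputs are z-scored first) |
| `input_bias` | 0.5 | per-unit constant drive breaking odd symmetry |
| `leak_rate` | 0.3 | leaky-integrator rate; slower leak = longer memory |
| `ridge_lambda` | 1e-2 | readout shrinkage |
| `washout_frames` | 10 | states discarded after each block reset |
| `n_reservoirs` | 5 | realisations averaged |

### Numerical choices

* Both series are z-scored once with statistics pooled over all blocks
  of the dyad. This makes $F$ exactly invariant to rescaling either
  input. Fold-wise re-standardisation would change the scaling constants
  by $O(1/B)$ at twelve times the state-computation cost, because every
  reservoir state would have to be recomputed per fold; the pooled
  variant keeps states reusable across folds while the MSE *ratio*
  remains insensitive to the common scale.
* The reservoir state is reset to zero at every block start and the
  first `washout_frames` states of each block are discarded, so blocks
  are causally independent; permuting block order changes nothing
  (leave-one-block-out folds are a set, not a sequence), which the test
  suite checks to 1e-10.
* Zero-variance channels (a face feature the extractor never moved)
  yield flagged-missing (`NA`) matrix cells rather than fabricated
  values; inference excludes them and reduces the FDR family
  accordingly.
* The intercept column of the readout is not penalised.

### A small-reservoir artifact worth knowing about

Adding a second, uninformative input to a *small* reservoir measurably
degrades held-out prediction of the target: the two inputs compete for
representational capacity. Uncoupled cells therefore sit slightly below
zero, and the effect is stronger when the extra input is independent of
the target than when it is correlated with it. Both real-dyad and
pseudo-dyad estimates share this bias, so the rank-based contrast
absorbs it; at `n_units` of 20 and above the residual real-vs-null shift
in uncoupled cells is an order of magnitude below the planted-cell
separation. It is one more reason the package never interprets raw GC
magnitudes, only their contrast against the pseudo-dyad null.

## Pseudo-dyad null and link inference

For each direction the cohort yields one GC value per dyad per matrix
cell. The empirical null is built from *pseudo-dyads*: all ordered
pairings of a patient and a clinician who never interacted
($n(n-1)$ for $n$ real dyads, optionally subsampled with a seeded cap).
Pseudo-dyads preserve the shared protocol structure — each member keeps
their own session timing, blocks are paired by block index and truncated
to the shorter member — so "pseudo-concordance" induced by the common
protocol is present in the null and cancelled by the contrast.

Each cell is tested with a one-sided Mann-Whitney rank-sum test
(real > null), exact when $\min(n, m) \le 8$ without ties and by normal
approximation with tie and continuity correction otherwise. The
resulting 20 x 20 grid of p values is corrected by Benjamini-Hochberg
step-up across all 400 cells of the direction (each direction is its own
family), with significance at $q \le \alpha = 0.05$. The per-dyad scalar
used downstream — the *AU28 row score* — is the mean GC strength from
the patient's lip-suck channel to all 20 clinician AUs.

Two conventions deserve a note. First, the exact Mann-Whitney p value is
inclusive, $p = P(W \ge W_{obs})$, matching both `wilcox.test()` and the
enumeration oracle in the test suite; a maximally *reversed* sample thus
has $p = 1$, not $1 - 1/\binom{n+m}{n}$. Second, BH uses the step-up
"$\le$" convention, so a single cell at exactly $\alpha/m$ is
significant; the suite cross-checks the decision against a brute-force
step-up implementation on a thousand random grids.

## Pain classification and SHAP ranking

Frames inside moderate-pain and innocuous-pressure stimulation blocks
form the classification table (one row per frame, 20 AU features); rest,
anticipation and rating frames are excluded. Frames rather than blocks
are the unit because the question is *state* discrimination, and the
block count per subject (12) is far too small to train on. Validation is
grouped k-fold (default k = 5) at the *subject* level, so identity
leakage across folds is impossible; AUC is threshold-free and pooled
over held-out predictions, precision and recall use the 0.5 posterior
threshold by default. The model is XGBoost with shallow trees (depth 3,
200 rounds, learning rate 0.1) — enough capacity for smooth AU shifts
without memorising subjects. AU importance is the mean absolute TreeSHAP
contribution per channel over all frames, ranked descending with ties
broken alphabetically.

## Beta series and cross-brain concordance

Each subject's parcel-level BOLD is reduced to 12 trial betas by an OLS
GLM with one regressor per anticipation trial (boxcar convolved with the
canonical double-gamma HRF, shapes 6 and 16, undershoot ratio 1/6,
peak-normalised) plus pooled pain and rating nuisance regressors and an
intercept. The generator can emit raw BOLD so this stage is exercised
end to end; by default it emits betas directly to keep experiments fast.

Cross-brain concordance regresses one subject's z-scored trial betas,
parcel by parcel, on the partner's z-scored ROI trial vector; with both
sides standardised the slope *is* the Pearson correlation across the 12
trials, and the test suite holds the closed-form equality to 1e-12.
Group inference is an OLS regression of the per-dyad parcel coefficients
on the z-scored AU28 row score with BH-FDR across parcels. This
parcel-level formulation plays the inferential role of a voxelwise
mixed-effects map with cluster correction at desk scale; it does not
model within-dyad variance heterogeneity, and parcels stand in for
voxels. Dyad-level scalar concordance for a named ROI pair (clinician
anterior insula vs patient mid/posterior insula by default) enters
two-sided Pearson correlations with the CARE therapeutic-alliance score
(patient- and clinician-rated totals averaged per dyad) and the Berkeley
negative-expressivity subscale.

## The synthetic cohort: what it emulates, and what it does not

`generate_dyad_au()` models each AU channel as a stationary AR(1)
(coefficient 0.8, innovation sd 0.6, hence unit marginal variance) on
top of the session protocol: per trial rest, a 6-12 s pseudorandomised
anticipation cue, a stimulation phase and a rating phase, 6 trials per
run, two runs. A planted directed edge adds
`gain * tanh(source lagged by lag_frames)` to the target innovation,
by default only inside anticipation blocks — exactly where the GC stage
looks. The default edge set plants the leader-follower pattern the
analysis should recover: patient AU28 driving clinician AU43 and AU7.
Durations are snapped to the frame grid so the
`n_frames = round(duration * rate)` invariant is exact.

`generate_pain_session()` shifts the four pain-expressive channels
(AU28, AU43, AU7, AU4) by 1.5/1.2/1.0/0.8 marginal-sd units during
moderate-pain stimulation, with per-trial jitter (sd 0.3); all other
channels are identical in distribution across conditions, so any
importance assigned to them is a false positive.

`generate_dyad_brain()` draws a shared per-trial latent for the
clinician's anterior-insula parcels and mixes it into the patient's
mid/posterior-insula parcels with correlation
`rho = tanh(concordance_gain * facial_score)`; all other parcels are
independent noise. CARE and Berkeley scores are linear in `rho` plus
rater noise, clamped to instrument ranges (CARE totals 9-45, Berkeley
negative expressivity 6-42). The slopes (CARE 10, negative expressivity
18) were chosen once so that a 40-dyad cohort lands at observed
correlations around 0.5-0.65 — the magnitude regime reported for real
patient-clinician cohorts — rather than at trivially saturated values.

Per-dyad heterogeneity comes from a uniform gain scale (0.4-1.6)
multiplying the planted edges; the dyad's facial score (mean realised
gain) then drives both the brain coupling and behaviour, tying all
stages to one ground truth.

What the generator does *not* emulate: facial biomechanics or realistic
AU co-activation structure, extractor noise and dropped frames, fMRI
autocorrelated or physiological noise, motion, or clock drift between
scanners (streams are generated pre-synchronised, and the data model
deliberately refuses to resample). Passing tests therefore demonstrate
that the estimators recover the dependence structure they were designed
for, not that they are robust to every artefact of real recordings.

One property of the AR(1)-innovation coupling is easy to trip over: the
cross-correlogram of a planted lag-$\ell$ edge peaks at $\ell$ only
while the AR coefficient is below $(\sqrt 5 - 1)/2 \approx 0.618$;
above that, filtering through the target's AR kernel shifts the apparent
peak later even though the causal lag is unchanged. This is a feature of
the model, not a bug in the estimator — and one more argument for
model-based causality estimation over reading lags off correlograms.

## Experiment sizes

The packaged experiments (test suite and `scripts/acceptance.R`) use
sizes chosen to make each property measurable in minutes on one core:
single-pair oracle checks run at the full default reservoir (100 units,
5 realisations, 12 blocks of 200 frames, 20 seeds); grid-scale cohort
experiments use reduced reservoirs — 10 units for the null calibration,
where exchangeability of real and pseudo dyads makes the test level
independent of the estimator's configuration, and 20 units for the
planted-edge recovery, where the pilot separation between planted and
null cells is large. The estimator defaults themselves are unchanged by
any of this. Session timing outside the anticipation blocks (rest,
stimulation, rating durations) is compressed in the experiments; the
anticipation blocks, which carry all analysed frames, keep the 6-12 s
protocol range.

## Known limitations

* GC is bivariate per cell, as the 400-cell grid demands; it does not
  condition on the other 18 channels, so indirect paths can appear as
  links. Conditional or multivariate GC is out of scope.
* The Mann-Whitney contrast treats dyads as exchangeable; it has no
  notion of per-dyad precision.
* The concordance stage assumes trial betas are comparable across
  subjects after within-subject z-scoring; scanner- or run-level
  effects are not modelled.
* Behavioural instruments are simulated as clamped linear responses;
  floor/ceiling behaviour of real questionnaires is cruder here.
* `run_pipeline()` executes in-memory cohorts only; it orchestrates the
  stages and their dependencies but is not a workflow manager.
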