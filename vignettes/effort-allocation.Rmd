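---
title: "Modeling effort allocation under auricular vagus nerve stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling effort allocation under auricular vagus nerve stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effortvns)
```

## The task and its two motivational readouts

In the effort-allocation task a participant repeatedly presses a button to
keep a ball above a difficulty threshold; each second spent above the
threshold earns food or money points. The press-rate series of a trial —
relative button-press frequency in % of the participant's practice-estimated
maximum, sampled over a 30-s effort phase — is summarized by two indices:

* **Invigoration** (%/s): how quickly effort is energized — the slope of the
  transition from rest to the initial plateau of the subsequent work bout,
  averaged over the trial's rest-to-work transitions.
* **Effort maintenance** (% of maximum): how durably effort is kept up — the
  arithmetic mean of the relative press frequency over the whole effort
  phase.

The two indices dissociate the benefit and cost sides of effort: in this
design invigoration tracks reward magnitude and rated wanting, whereas
maintenance additionally reflects difficulty and rated exertion.

Each participant completes two sessions in a randomized single-blind
crossover — one under transcutaneous auricular vagus nerve stimulation
(taVNS, cymba conchae) and one under sham (earlobe) — with 48 trials per
session crossing reward type (food/money), reward magnitude (low/high, 1 vs
10 points per second) and difficulty (easy/hard, threshold at 75% vs 85% of
the individual maximum), six trials per cell. Stimulation order and ear side
are between-participant covariates.

## The cost-evidence accumulation model

Decisions to stop and resume effort are modeled by a latent cost-evidence
signal: it accumulates during work with slope SE until it reaches an
amplitude bound A (triggering rest), and dissipates during rest with slope
SR (triggering resumption). Bout durations are therefore

$$\text{work} = A / S_E, \qquad \text{rest} = A / S_R.$$

The amplitude intercept is fixed to 1, so slopes are expressed relative to
it. Reward magnitude modulates A and SR, difficulty modulates SE, and the
stimulation condition adds an additive term to every free parameter,
e.g. $S_{E,\mathrm{mean}} = S_{E,\mathrm{sham}} + \mathrm{Stim} \times
S_{E,\mathrm{taVNS}}$ with Stim coded sham = 0, taVNS = 1. Restricting the
condition modulators this way (rather than letting every factor modulate
every parameter) keeps the parameters identifiable and the chains stable.

**Duration likelihood.** Observed bout durations are taken as log-normal
around the model-implied duration with a shared log-scale standard
deviation. The log-normal respects positivity and the right skew of bout
durations; the likelihood is swappable (a gamma alternative would slot into
the same interface) but log-normal is the default throughout.

**Hierarchy and priors.** Participant-level parameters are normal around
group-level means; group means carry weakly informative normal priors (the
taVNS terms centered at 0 with scale 0.707, matching the Bayes-factor
comparison prior), group standard deviations and the duration noise are
half-normal. Positivity of every realized A, SE, SR is enforced by a scaled
softplus link ($s\,\log(1+e^{x/s})$ with $s$ = 0.05 for A and 0.02 for the
slopes) — near-exact identity in the plausible range, smooth near zero, so
the MCMC geometry stays well behaved. The fixed amplitude intercept maps to
softplus(1) ≈ 1 + 2e-9 at the A scale, a negligible offset.

**Estimation.** The model is fitted by MCMC (JAGS) with, by default, 2
chains × 1500 retained draws at thinning 2 after 500 adaptation and 500
burn-in iterations. The bout-level log-normal likelihood is evaluated
through exact sufficient statistics — per participant × bout-type ×
condition cell, the mean log duration (normal, precision $n\tau$) plus the
pooled within-cell sum of squares (gamma) — which is algebraically identical
to the observation-level likelihood under the shared log-sd and keeps the
graph small. Convergence is gated on split-$\hat R \le 1.05$ over the group
parameters; a fit exceeding the gate is returned flagged, never silently.
The three additive taVNS terms trade off against each other through the
shared amplitude (an almost-ridge in the likelihood), so they mix more
slowly than the intercepts; thinning is the pragmatic remedy, and fits used
for calibration keep the flag visible.

**Bayes factors.** Evidence for a stimulation effect on a cost-evidence
parameter is the Savage–Dickey density ratio at 0: the density of a
Cauchy(0, 0.707) comparison prior at 0 divided by the posterior density at
0, the latter from a Gaussian kernel density estimate (Silverman bandwidth)
evaluated exactly at 0. This operationalizes "comparing the posterior to a
Cauchy prior"; it is an interpretation, and it is exact only insofar as the
KDE is accurate near 0 (when the posterior has no estimable mass near 0 the
returned value is a flagged lower bound).

## The synthetic-data generator

The generator is first-class, tested code: it produces complete two-session
crossover datasets from known ground truth so that every inferential engine
in the package can be checked by parameter recovery. Defaults are the study
conditions the analyses assume:

| parameter | default | unit | rationale |
|---|---|---|---|
| ramp intercept | 55.3 | %/s | invigoration intercept scale of this design |
| reward-magnitude effect | +5.8 | %/s | benefit effect on invigoration |
| difficulty effect | −2.4 | %/s | cost effect, about half the benefit effect |
| taVNS effect | +2.9 | %/s | stimulation main effect on invigoration |
| taVNS × food | +1.3 | %/s | stronger taVNS effect for food rewards |
| participant ramp sd | 8 | %/s | between-participant vigor differences |
| participant taVNS-effect sd | 2 | %/s | individual stimulation responses vary |
| SE (sham), SR (sham) | 0.15, 0.40 | 1/s | work ≈ 6.7 s, rest ≈ 2.5 s bouts |
| SE difficulty, SR reward, A reward | +0.05, +0.10, +0.20 | — | condition modulators of the cost-evidence process |
| taVNS terms on A, SE, SR | 0 | — | no stimulation effect on cost evidence |
| duration noise (log-sd) | 0.25 | — | right-skewed bout-length variability |
| plateau jitter | 4 | % points | within-bout press-rate noise |

Work bouts ramp linearly from 0 at the trial's ramp rate to a plateau 5
percentage points above the difficulty threshold (so work reliably accrues
reward) and hold it, jittered, until the bout duration — drawn log-normally
around $A/S_E$ — elapses; rest bouts drop the raw press rate to 0 (the
on-screen ball, i.e. the EMA-smoothed series with weight λ = 0.6, decays
geometrically). A trial-level motivation fluctuation (sd 6 %/s) loads on
the ramp rate, on wanting ratings, and weakly on log work duration; exertion
ratings load on difficulty and realized maintenance. This yields the
dissociation the analyses assume — invigoration relates to wanting but not
exertion, maintenance to both — and gives the wanting–invigoration coupling
the utility-slope analysis estimates. Ratings sit on a 0–10 visual analog
scale (the scale is dataset metadata, not an assumption baked into the
models).

What the generator does **not** emulate: fatigue and time-on-task drift,
session effects beyond stimulation, serial dependence between trials,
response lapses or device artifacts, floor/ceiling compression of ratings
beyond simple clipping, and any stimulation-side lateralization. Passing
recovery tests therefore show the estimators are correct and calibrated
under the generative model's assumptions — not that those assumptions hold
for any particular real dataset.

Simulation is deterministic: every participant/session stream derives its
seed from the master seed, so identical seeds give bit-identical datasets.

## Extraction choices

Segmentation thresholds the EMA-smoothed series at 10% of maximum (runs
shorter than 0.3 s are merged into their neighbors, shortest first); the
threshold separates true rest from button-release jitter and both knobs are
exposed in the task configuration. The plateau of a work bout is its first
local maximum with prominence ≥ 5 percentage points over the segment onset
(segment maximum as fallback). The invigoration line is fitted on the raw
series over the rising limb only, stopping below 90% of the rise to the
plateau value: plateau samples are rate-capped, and including them biases
the slope toward zero by an amount that grows with the true ramp rate —
with them included, condition effects on invigoration would be
systematically attenuated. Trials with no work segment yield missing
indices rather than zeros, so empty trials cannot drag slopes toward zero.
On noise-free, grid-aligned trials the extracted indices equal the
generative values to numerical precision; with bout-duration and plateau
noise at default levels the mean extracted ramp stays within a few percent
of truth.

## The inferential engines

**Mixed models.** Trial-level outcomes are fitted by REML (lme4) with
dummy-coded fixed effects for stimulation, reward type, reward magnitude,
difficulty, reward magnitude × difficulty, and stimulation × each of these;
stimulation order and side enter mean-centered at the participant level.
Intercepts and trial-level slopes are random by participant; the full
unstructured covariance is attempted first and a singular or non-converged
fit falls back to a diagonal covariance (recorded in the result). t
contrasts are two-tailed with participant-level approximate degrees of
freedom $n - q - 1$ (q = participant-level covariates), the
hierarchical-linear-models convention — chosen deliberately over
Satterthwaite so that inference is anchored at the participant level.
Nested structures are compared by likelihood-ratio χ² after ML refits.
With dummy coding the `stimulation` coefficient is the taVNS − sham
contrast in the reference cells; `stim_contrast()` additionally reports
the marginal stimulation effect (averaged over condition cells). The
marginal contrast loads with weight 1 on the participant-level stimulation
slope, so its standard error is governed by the random-slope variance and
is well calibrated — it is the quantity whose type-I error the test suite
verifies. The reference-cell coefficient's standard error additionally
mixes cell-level residual loadings and runs mildly conservative on data
whose noise structure departs from the homoscedastic model (as the
generator's does, through its cost-evidence channels).
Two-sided α = 0.05 without multiplicity correction for the primary
contrasts; a Holm flag is available for exploratory interactions.

**Individual effects and JZS Bayes factors.** Per-participant OLS
stimulation effects (residualized for stimulation order across
participants, grand mean restored) feed a one-sample
Jeffreys–Zellner–Siow Bayes factor with Cauchy(0, 0.707) effect-size
prior, computed by numerical integration of the non-central t likelihood
over the prior. An independent formulation (the inverse-gamma mixture over
the variance scale) agrees to machine precision and serves as the test
oracle.

**Effort-utility slope.** The group-level association between invigoration
and wanting per stimulation condition is fitted by Huber-weighted
iteratively reweighted least squares (tuning constant 1.345 on
MAD-standardized residuals) with stimulation order as nuisance covariate;
group-level fitting is preferred because restricted individual rating
ranges make many individual slopes uninformative. Significance of the
taVNS − sham slope difference comes from a permutation test (default
10,000 refits): stimulation labels are swapped within participant
(session-wise flips), which respects the crossover design's exchangeability
— a free label permutation is available behind a flag but is not the
default. The two-sided p-value uses the add-one convention
$(1 + \#\{|b^\ast| \ge |b|\})/(B+1)$, which is never exactly zero. The
stimulation × reward-type interaction is tested as a difference of slope
differences under the same scheme.

## Calibration and problem sizes

The test suite checks, among others: exact recovery of indices on
noise-free trials; convergence of condition-mean differences to the
configured generative effects (500 simulated participants, three
Monte-Carlo standard errors); posterior recovery of the cost-evidence
intercepts within 15% with truth–estimate correlations above 0.8 (20
participants × 2 × 48 trials) and ≥ 90% credible-interval coverage of a
true-zero taVNS term over 20 replicates at reduced draws; uniformity of the
permutation p-value under a sharp null generator (200 replicate datasets ×
500 permutations, Kolmogorov–Smirnov); and nominal type-I error of the
mixed-model stimulation contrast under a hierarchical null — individual
taVNS effects vary but average zero, matching the random-slope structure
the model assumes — over 200 replicates of 12 participants. The two null
flavors are deliberate: the permutation test assumes the sharp null
(exchangeable labels), the mixed-model t-test only the zero-mean null.

## Limitations

* The bout-duration likelihood and the additive taVNS parameterization are
  the package's operationalization of the cost-evidence framework; the
  linear A/S duration form is adopted from the established accumulation
  model of effort allocation.
* The three additive taVNS terms are only weakly separable (two observable
  duration shifts inform three parameters); group-level priors regularize
  them, their posteriors mix slowly, and their Bayes factors should be read
  jointly rather than term by term.
* The Savage–Dickey ratio uses a kernel density at a point; with very
  peaked or very diffuse posteriors the estimate inherits the KDE's
  bandwidth sensitivity.
* The generator's defaults describe one plausible operating regime;
  calibration results are statements about that regime, not about every
  possible dataset.
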