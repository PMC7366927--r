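# effortvns

Simulation and analysis of effort-allocation experiments with
transcutaneous auricular vagus nerve stimulation (taVNS) versus sham in a
randomized two-session crossover. The package is aimed at researchers in
effort-based decision making who want a tested, reproducible pipeline for
this design: a synthetic-data generator with known ground truth, extraction
of trial-level motivation indices from button-press-rate series, and the
three inferential engines the design calls for.

## What it computes

Participants press a button to keep a ball above a difficulty threshold
(75% or 85% of their maximum press frequency) and earn food or money
points for every completed second above it. Two indices summarize each
trial's press-rate series (% of maximum, EMA-smoothed with λ = 0.6 for
display and segmentation):

* **Invigoration** (%/s) — the slope of the rest-to-work transition up to
  the initial plateau of the work bout: how quickly effort is energized.
* **Effort maintenance** (%) — the trial-average relative press frequency:
  how durably effort is kept up.

Work/rest bout durations follow a cost-evidence accumulation model: a
latent cost signal rises during work with slope SE to an amplitude bound A
(work = A/SE) and dissipates during rest with slope SR (rest = A/SR), with
A fixed to 1 at baseline, reward magnitude modulating A and SR, difficulty
modulating SE, and additive taVNS terms on all free parameters
(X = X_sham + Stim · X_taVNS, Stim ∈ {0, 1}).

The analysis stages:

1. **Mixed-effects models** (REML, random intercepts and condition slopes
   by participant) of invigoration, maintenance, wanting and exertion on
   stimulation × condition dummies, with mean-centered stimulation order
   and side as participant-level covariates; two-tailed t contrasts at
   participant-level df, likelihood-ratio χ² for nested comparisons, and
   one-sample Jeffreys–Zellner–Siow Bayes factors (Cauchy prior,
   r = 0.707) on order-corrected individual stimulation effects.
2. **Effort-utility slope**: group-level Huber robust regression of
   invigoration on rated wanting per stimulation condition, with a
   within-participant permutation test of the taVNS − sham slope
   difference.
3. **Hierarchical Bayesian cost-evidence fit** (MCMC via JAGS) with
   Savage–Dickey Bayes factors for the taVNS parameters and
   posterior-predictive recovery of mean segment lengths.

## Worked example

```r
library(effortvns)

dataset <- simulate_dataset(24, seed = 1)     # 24 participants x 2 x 48 trials
fit <- fit_stim_model(dataset, "invigoration", random = "diagonal")
print(fit$coefficients[fit$coefficients$term == "stimulation", ])
#> # A tibble: 1 x 6
#>   term            b    se     t    df      p
#>   <chr>       <dbl> <dbl> <dbl> <dbl>  <dbl>
#> 1 stimulation  1.99 0.832  2.39    21 0.0262
```

The `stimulation` row is the taVNS − sham contrast in the reference cells
(money/low/easy): here invigoration is about 2.0 %/s faster under taVNS
(t(21) = 2.38, p = 0.026; the generator's true effect is 2.9 %/s with
between-participant sd 2). The matching Bayes factor on individual effects
and the utility-slope permutation test follow the same pattern:

```r
eff <- individual_stim_effects(dataset, "invigoration")
jzs_bayes_factor(eff$effect)
#> [1] 495.5101

permutation_test(dataset, n_perm = 2000, seed = 1)
#> <utility_slope_result> stimulation main effect
#>   sham slope 3.017 | taVNS slope 3.122 (%/s per VAS unit)
#>   observed taVNS - sham difference: 0.1050
#>   p_perm = 0.7221 (2000 permutations, mode 'within', seed 1)
```

(The default generator does not alter the wanting–invigoration coupling
under taVNS, so the permutation p is unremarkable by construction.)
The cost-evidence model is fitted on the realized bout table and recovers
its generating parameters:

```r
ce <- fit_cost_evidence(dataset$truth$bouts, seed = 1)
ce$summary[ce$summary$parameter %in% c("se_sham", "sr_sham", "se_tavns"), ]
#>  parameter    mean      sd  ci_lower ci_upper rhat  n_eff
#>    se_sham 0.14709 0.00451  0.138170   0.1560 1.00 2386.7
#>   se_tavns 0.00758 0.00505 -0.000854   0.0177 1.58   19.7
#>    sr_sham 0.39950 0.01563  0.370036   0.4319 1.00 2578.2
tavns_bayes_factor(ce, "se_tavns")
#> [1] 0.01407321
```

The intercepts recover the generating truth (SE 0.15, SR 0.40) and the
taVNS term's credible interval contains 0 with a Bayes factor far below 1 —
no stimulation effect on cost-evidence accumulation, matching the
generating truth. The additive taVNS terms trade off through the shared
amplitude and mix slowly (note their R-hat: at default draws this fit is
flagged non-converged for exactly those terms); increase `n_draws`/`thin`
when they are the quantity of interest.

`run_pipeline(out_dir)` chains all stages and writes a report directory
(trial tables, coefficient/Bayes-factor report, cost-evidence posterior
and recovery tables), each file stamped with the configuration hash and
seed.

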