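# flankrel

Reliability analysis for flanker-style difference scores from trial-level
reaction times.

## The problem

Two-condition speeded tasks — the arrow flanker task is the canonical case —
are scored with a difference score: mean correct RT on incongruent trials
minus mean correct RT on congruent trials. Difference scores cancel
person- and device-level speed offsets, which makes them the right choice
for web and smartphone administration, but they are often poor measures of
*individual differences*: between-person variance in the effect is small
against trial noise, so a task that demonstrates a group effect at p < .001
can still rank individuals close to randomly. Quantifying exactly how
reliable such a score is — across sessions, within a session, and as a
function of task length — is the job of this package. It is aimed at
researchers designing or evaluating cognitive tasks for individual
differences work: how many trials does a target reliability require, do two
groups differ in reliability, and is a resampling-based split-half estimate
trustworthy for a short task?

## What it computes

- **Scoring** of long-format trial data with the standard exclusion rules:
  practice trials, RTs < 100 ms, incorrect responses, and RTs more than
  3×MAD above the individual's median (`rt − median > 3·MAD`, median and
  unscaled MAD per participant × session), plus the 60%-accuracy inclusion
  criterion, all in a single non-iterative pass.
- **Test–retest reliability** via the single-measure absolute-agreement
  intraclass correlation under a two-way model,

  ICC(A,1) = (MS_R − MS_E) / (MS_R + (k−1)·MS_E + (k/n)(MS_C − MS_E)), k = 2,

  and the Pearson correlation.
- **Split-half reliability** by repeated random splitting stratified by
  congruency × direction — disjoint *permutated* halves or
  with-replacement *Monte Carlo* halves — Spearman–Brown adjusted and
  aggregated over (by default) 10,000 replications.
- **Reliability-by-length curves** from stratified trial subsampling
  (40, 80, …, 320 trials), fit against the 101 Spearman–Brown prophecy
  curves ρ\*(n) = nρ / (1 + (n−1)ρ) for ρ = 0.00, 0.01, …, 1.00 by least
  squared error, plus the inverse problem (smallest trial count reaching a
  target reliability).
- **Comparison and planning**: one-sided z-tests on Fisher-z-transformed
  correlations from independent samples (effect size Cohen's
  q = atanh r₁ − atanh r₂) and the matching per-group sample-size rule
  n = ⌈2((z₁₋α + z_power)/q)² + 3⌉.
- **Leverage analysis**: leave-two-out resampling of the ICC to detect
  outlier participant pairs that carry a reliability estimate.
- **A synthetic trial-level generator** (ex-Gaussian noise, contaminant
  lapses, per-condition error rates, session speed-up, optional unstable
  outlier participants) with a closed-form true reliability that accounts
  for the exclusion pipeline, so every estimator is testable by parameter
  recovery. See the methods vignette (`vignettes/flankrel-methods.Rmd`)
  for the model and all design decisions.

## Worked example

Simulate a 60-participant two-session study whose true reliability at 160
trials/condition is calibrated to 0.6, score it, and estimate reliability
both ways:

```r
library(flankrel)

params <- calibrate_effect_sd(flanker_params(seed = 2024, n_participants = 60),
                              target = 0.6)
trials <- flag_rt_exclusions(simulate_flanker(params, group = "demo"))
scores <- score_participants(trials)
head(scores[, c("participant", "session", "mean_rt_congruent",
                "mean_rt_incongruent", "flanker_effect", "accuracy")], 4)
#>   participant session mean_rt_congruent mean_rt_incongruent flanker_effect accuracy
#> 1       P0001       1             588.0               634.5          46.51   0.9906
#> 2       P0001       2             577.8               619.3          41.59   0.9969
#> 3       P0002       1             577.9               608.4          30.49   0.9969
#> 4       P0002       2             551.4               587.9          36.54   0.9906

w <- merge(scores[scores$session == 1, c("participant", "flanker_effect")],
           scores[scores$session == 2, c("participant", "flanker_effect")],
           by = "participant")
icc_absolute_agreement(w$flanker_effect.x, w$flanker_effect.y)
#> <reliability_estimate> test_retest (icc_abs_agreement) = 0.6125, n = 60

splithalf_reliability(trials, split_spec(n_replications = 1000, seed = 7))
#> <reliability_estimate> split_half (pearson) = 0.6245, n = 60; method = permutated,
#>   n_replications = 1000, adjust = spearman_brown, aggregate = mean, session = 1,
#>   seed = 7, n_dropped_replications = 0
```

Both estimators land near the calibrated truth of 0.6: the test–retest
ICC(A,1) treats the two sessions as raters and penalizes mean shifts; the
split-half value is the mean over 1,000 random stratified splits of
session 1, stepped up to full length. Planning questions have closed-form
answers:

```r
sb_required_length(rho_full = 0.61, rho_target = 0.8, full_trials = 320)
#> [1] 819        # trials needed for predicted reliability 0.8
required_n_per_group(q_effect = 0.3, alpha = 0.05, power = 0.8)
#> [1] 141        # participants per group for the correlation comparison
```

`run_pipeline()` chains all stages (simulate/load → score → descriptives →
test–retest → split-half → length curves → group comparisons → power) from
a YAML/JSON config and writes a fully seeded JSON report;
`inst/cli/flankrel.R` exposes the same stages as shell subcommands.

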