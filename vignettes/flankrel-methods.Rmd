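---
title: "Measuring the reliability of flanker-style difference scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the reliability of flanker-style difference scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flankrel)
```

## The problem

Two-condition reaction-time tasks such as the arrow flanker task are scored
with a *difference score*: the mean correct RT in the incongruent condition
minus the mean in the congruent condition. Difference scores are robust to
device- and person-level speed offsets, which makes them attractive for
web- and smartphone-administered testing, but they are notoriously
unreliable as measures of *individual differences*: the between-person
variance of the effect is small relative to trial-level noise, so tasks that
detect a group-level effect easily can still rank people almost at random
(the so-called reliability paradox). flankrel implements the full
measurement-side toolbox for studying this problem: trial-level scoring
with the standard exclusion rules, test-retest and split-half reliability
coefficients, resampling-based reliability-by-length curves with
Spearman-Brown prophecy fits, tests and power analysis for comparing
reliabilities across independent groups, and a synthetic trial-level
generator with a closed-form true reliability so that every estimator in
the package can be validated by parameter recovery.

## Scoring and exclusion rules

Scoring operates on long-format trial tables (one row per trial). Main-block
trials only are scored; practice trials are flagged and never enter any
statistic. Three exclusion rules are applied in a single pass, on the
pre-exclusion trial set, so removing one flagged trial never changes another
trial's flag:

* RTs below 100 ms (anticipations);
* incorrect responses;
* RTs more than 3 times the individual's median absolute deviation above
  the individual's median (`rt - median > 3 * MAD`), the "slow tail" rule.

Three readings of the 3 MAD rule required a decision:

* **Tail direction.** A literal `rt > 3 * MAD` would exclude almost every
  trial (the MAD of RTs is tens of milliseconds); the rule is implemented as
  an upper-tail deviation cut, with the fast tail handled separately by the
  100 ms floor. This matches how descriptive tables in the flanker
  literature report "% RT > 3MAD" alongside a separate "% RT < 100 ms"
  column.
* **MAD scope.** The median and MAD are computed per participant x session,
  pooled across conditions -- the rule names the individual, not the
  condition. A `mad_per_condition` switch computes them within condition
  instead.
* **MAD set.** By default the statistics (and the flag) are restricted to
  correct trials, because error RTs come from a different generating
  process; `mad_correct_only = FALSE` pools them in. The MAD is unscaled
  (no 1.4826 normal-consistency factor): the rule as used in this
  literature is a plain median of absolute deviations.

The accuracy criterion retains a participant only when accuracy is at least
60% in *both* sessions; exactly 60% is retained ("below" is strict), and
participants missing a session are reported separately as incomplete.

## Reliability coefficients

The primary test-retest coefficient is the single-measure intraclass
correlation for absolute agreement under a two-way model, ICC(A,1),
computed from the ANOVA mean squares

$$\mathrm{ICC}(A,1) =
\frac{MS_R - MS_E}{MS_R + (k-1)\,MS_E + \tfrac{k}{n}(MS_C - MS_E)},
\qquad k = 2 .$$

The single-measure form is used because the object of reliability is an
individual's score from one administration, not the mean of both sessions.
Unlike a Pearson correlation, ICC(A,1) penalizes between-session mean
shifts; with no shift and equal variances the two coincide, which the test
suite checks on constructed cases. Zero between-participant variance makes
the coefficient undefined; the package returns `NaN` with a warning rather
than a fabricated value.

Independent-sample comparisons of correlations use the Fisher z transform:
the effect size is Cohen's $q = \operatorname{atanh} r_1 -
\operatorname{atanh} r_2$ and the statistic $q / \sqrt{1/(n_1-3) +
1/(n_2-3)}$ is referred to the standard normal, one-sided by an explicit
`alternative` argument. The matching sample-size rule,
$n = \lceil 2\,((z_{1-\alpha}+z_{\beta})/q)^2 + 3\rceil$ per group, is
solved analytically. Reported `q` values are conventionally rounded to two
decimals; all internal computation is at full precision. Recomputing a
p-value from correlations that were themselves rounded to two decimals can
move it by a few hundredths, so printed p-values are treated as
approximately reproducible only.

## Split-half resampling

Split-half reliability is estimated by repeated random splitting of one
session's valid trials, stratified by congruency x target direction so that
every half is balanced on the design factors:

* **Permutated splitting**: each stratum is partitioned at random into two
  disjoint halves whose sizes differ by at most one (the odd trial lands in
  a half at random). Halves are then scored exactly like full sessions, the
  half effects correlated across participants, the coefficient stepped up
  with the Spearman-Brown formula at length ratio 2, and the replications
  averaged.
* **Monte Carlo splitting**: each half is an *independent sample with
  replacement* of $\lceil m/2 \rceil$ trials per stratum. The two halves
  can share trials, which induces a positive covariance between half scores
  that does not shrink as the task gets shorter -- the mechanism behind the
  inflated Monte Carlo estimates for short tasks shown by the length-curve
  analyses. The sampling scheme for Monte Carlo halves is not uniquely
  defined in the literature; half-length halves drawn per stratum are the
  default here, and `mc_half_size = "full"` switches to full-length halves.

Aggregation over replications is a simple mean by default; a Fisher-z mean
(back-transformed) is available, and on realistic data the two differ by
less than 0.01, which the test suite asserts. Replications with zero
between-person variance, or where fewer than three participants have
scorable halves, are dropped and counted in the estimate's provenance.
Split-half estimation uses session 1 by default (`session` is selectable).
Whether published split-half values are Spearman-Brown adjusted is often
unstated; the package default is `adjust = "spearman_brown"`, and the
choice is recorded in every estimate's metadata.

## Reliability as a function of task length

Shortened tasks are constructed by stratified subsampling without
replacement: a task of total length $L$ takes $L/4$ trials from each
congruency x direction stratum, so a full-length draw is the original data
in randomized order. Per length and replication the package computes one
coefficient -- a test-retest correlation (with independent subsamples per
session, mirroring how a shorter task would actually have been administered
twice), or a single permutated or Monte Carlo split of the subsample -- and
averages over replications. Subsampling operates on all main trials;
flagged trials inside a draw simply contribute nothing to the half means,
exactly as if the shortened task had been run through the same exclusion
pipeline.

The resulting curve is compared against the family of Spearman-Brown
prophecy curves
$$\rho^*(n) = \frac{n\rho}{1 + (n-1)\rho}$$
over the grid $\rho \in \{0.00, 0.01, \ldots, 1.00\}$ (101 candidates),
with $n = L / L_{\text{full}}$; the best-fitting candidate minimizes the
sum of squared differences over lengths, ties breaking toward the smaller
$\rho$ (the conservative choice). A curve generated exactly from the
formula is recovered with zero error for every grid value. The inverse
problem -- the smallest integer trial count whose predicted reliability
reaches a target -- is solved in closed form and then verified by direct
evaluation, so floating-point rounding can never return a count one short.

## The synthetic generator and its closed-form truth

The generator emulates a two-session flanker study: 8 practice trials plus
two main blocks per session, each main block containing all 40 combinations
of direction (2), congruency (2) and fixation duration (10 values,
500-950 ms in 50 ms steps) exactly 4 times; order is a seeded uniform
shuffle per block (the pseudorandomization used in real presentations is
not further constrained, and no run-length constraints are imposed).

Per participant, a baseline speed $b_i$ and a flanker effect $d_i$ are
drawn once and shared by both sessions -- the trait assumption. A correct
trial RT is
$$\mathrm{RT} = b_i + d_i \cdot [\text{incongruent}]
- s_2 \cdot [\text{session 2}] + \varepsilon,$$
with ex-Gaussian noise $\varepsilon$ (Gaussian sd `sigma` plus exponential
mean `tau`) that is shifted by `contaminant_shift` with probability
`contaminant_rate` (attentional lapses). The session-2 term is a pure
speed-up applied equally to both conditions: real participants get faster
overall while their effect stays put, so the difference score is untouched.
Errors are Bernoulli per condition, with the incongruent rate at least the
congruent rate.

Default values were fixed once against the descriptive profile that
web-administered flanker studies report: condition means around 500-590 ms,
congruent-incongruent mean-RT correlations of 0.97-0.99, flanker effects
of 28-52 ms with between-person SDs of 13-21 ms, under 1.25% errors, and a
3-5% slow tail beyond the individual 3 MAD threshold. Two of those numbers
constrain the model in ways worth spelling out:

* A mean-RT correlation of 0.97+ is *unreachable* when baseline and effect
  are independent: the correlation is bounded by
  $1/\sqrt{1 + \sigma_d^2/\sigma_b^2}$, about 0.94 for any plausible SD
  ratio. Real data therefore imply a positive baseline-effect correlation
  (slower people show larger effects), and the generator has a
  `baseline_effect_cor` parameter, default 0.5.
* The 3-5% slow-tail share pins down the noise shape: `sigma = 70`,
  `tau = 40`, 1.5% contaminants at +300 ms give asymptotic exclusion rates
  of 3.1% (congruent) and 5.2% (incongruent), with the incongruent excess
  arising naturally because the shared threshold sits lower relative to the
  slower condition.

High-leverage outlier participants can be injected: the last
`n_outlier_participants` draw their effect with an inflated SD *and redraw
it independently in session 2*. Instability is essential -- a participant
with a huge but stable effect increases a test-retest coefficient, whereas
the empirically observed leverage scenario (a reliability that jumps when
one pair is excluded) requires scores that are extreme and inconsistent
across sessions. Relatedly, the outlier flagging in `leverage_analysis()`
uses a leave-one-out z-score: an ordinary z-score in a sample of $n$ is
bounded by $(n-1)/\sqrt{n}$ ($\approx 12.4$ at $n = 153$), so thresholds
like $|z| > 15$ are only meaningful against the remaining participants'
mean and SD.

### True reliability under the exclusion pipeline

For a task of $L$ trials per condition the classical ratio gives
$$\rho(L) = \frac{\lambda^2\sigma_d^2}
{\lambda^2\sigma_d^2 + V_c/L_c + V_i/L_i}.$$
The quantities are those of the scores the pipeline *actually produces*,
not of the raw noise: $V_c, V_i$ are variances of the noise mixture
truncated at the asymptotic exclusion threshold (the median plus 3 MAD of
the pooled two-condition mixture, found by root-finding on the mixture CDF
and integrated numerically to `rel.tol = 1e-10`); $L_c, L_i$ are the
expected retained trial counts $L(1-\text{error rate})P(\text{retain})$;
and $\lambda$ (about 0.90 at the defaults) is the attenuation of the trait
by the truncation -- a larger true effect pushes more incongruent trials
past the shared threshold, so the observed effect grows by less than a
millisecond per millisecond of trait. $\lambda$ is the local slope of the
expected observed effect in the trait, obtained by central differences.
Ignoring either correction produces a "truth" that parameter recovery
visibly misses: the truncation removes a large share of the exponential
tail's variance, and the attenuation costs about 0.05 in reliability at
realistic settings. Setting `adjust_for_exclusions = FALSE` gives the
textbook formula $\sigma_d^2/(\sigma_d^2 + 2V/L)$ on the raw noise
variance instead.

`calibrate_effect_sd()` inverts the formula to hit a target reliability
exactly, which is how recovery studies pin the truth at 0.6. Approximations
worth knowing: the threshold is evaluated at the population mean effect
(its mild dependence on the individual trait is ignored), threshold
sampling noise is ignored (it largely cancels between the two conditions,
which share the threshold within a session), and the sub-100 ms rule is
treated as measure-zero at realistic parameters. Parameter recovery at
$n = 200$ participants lands within one Monte-Carlo standard error of the
closed form, which is how these approximations were validated.

### What the generator does not emulate

Device and browser timing noise, between-device systematic offsets,
fatigue or practice drifts within a session, sequential effects
(post-error slowing, congruency sequence effects), RT-dependent accuracy
(fast guesses), and non-stationary lapse rates. Passing recovery tests on
synthetic data therefore shows that the estimators are correct for the
stated measurement model, not that real flanker data satisfy that model.

## Numerical choices and degenerate inputs

* ICC and Pearson coefficients require at least 3 complete pairs; zero
  variance yields `NaN` with a warning.
* `fisher_z()` rejects $|r| \ge 1$; the Fisher-mean aggregator nudges
  replication coefficients of exactly $\pm 1$ inside the domain by 1e-12
  rather than propagating infinities.
* The MAD is undefined below 4 trials and raises an error.
* Partitioning an odd stratum assigns the extra trial to a half at random;
  a stratum with fewer than 2 valid trials under permutated splitting makes
  that participant-replication unscorable, and such replications are
  skipped and counted, never silently imputed.
* All resampling runs through one compiled engine driven by R's RNG, so a
  single `seed` in the spec object makes every estimate bit-reproducible.
* Grid-fit ties break toward the smaller candidate reliability.

## Problem sizes used by the validation suite

The shipped tests validate parameter recovery with 200 simulated datasets
of 200 participants each (1,000 splits per dataset), qualitative
length-curve signatures with 1,000 replications per length on a 200
participant dataset, and oracle agreement of the ICC on 100 random small
datasets; these sizes give Monte-Carlo standard errors comfortably inside
the asserted tolerances (for example, the SE of the mean recovered ICC over
200 datasets is about 0.005 against a +/-0.03 band).

## Known limitations

Split-half and length-curve estimators assume a parallel measurement model
(halves and shortened tasks measure the same construct with equal
difficulty); confidence intervals for ICCs are not provided; the
trial-level model treats accuracy as independent of RT, so speed-accuracy
trade-offs are out of scope; and first-second or odd-even splitting is
deliberately not offered beyond the two resampling methods implemented,
which are the robust choices for difference scores.
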