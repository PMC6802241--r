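---
title: "Modelling eating-disorder life courses: methods and design choices"
author: "edmicrosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling eating-disorder life courses: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`edmicrosim` is an individual-level Markov state-transition microsimulation
of eating-disorder (ED) life courses. Each simulated person is followed in
annual cycles from birth to age 40 through six states: healthy, anorexia
nervosa (AN), bulimia nervosa (BN), binge eating disorder (BED), other
specified feeding and eating disorders (OSFED), and deceased (absorbing).
Cohorts are 50% male and 50% female, and every parameter is sex-specific.

Within one annual cycle, death is resolved first from the start-of-year
state; survivors then resolve a single multinomial draw:

* **Healthy, no ED history** — first-ever ("naive") onset of ED type $e$
  with probability $m_{e,s}\,g_e(a)$, where $g_e(a)$ is a fixed age shape
  (peak normalised to 1, emulating incidence curves that peak in
  adolescence) and $m_{e,s}$ a sex-specific level multiplier fitted in
  calibration.
* **Healthy, with ED history** — relapse into the most recent ED with
  probability $p_{\text{first}}\, e^{-\lambda (y-1)}$, where $y \ge 1$
  counts years since the last remission. The first year after remission
  carries the full first-year relapse probability; the hazard then decays
  exponentially at rate $\lambda \in [0,1]$.
* **Occupied ED state** — remission to healthy with probability
  $p_{\text{rem}}$ (untreated) or $1-(1-p_{\text{rem}})^{RR}$ (treated; the
  treatment effect is a rate ratio on the remission rate, converted
  probability → rate → probability), or direct diagnostic crossover to
  another ED with the per-pair annual probabilities, or persistence.
* **Mortality** — healthy persons die at the background life-table
  probability $q_s(a)$; persons in ED state $e$ at
  $1-(1-q_s(a))^{\mathrm{SMR}_{e,s}}$, i.e. a standardized mortality ratio
  applied on the rate scale.

Treatment under the baseline scenario is an independent annual
Bernoulli(coverage) draw per prevalent person-year. Whether treatment
status should instead persist across the years of a continuing episode is
not identified by the calibration targets; the annual redraw was chosen
because it matches the annual-cycle structure and keeps the expected
treated fraction equal to the coverage parameter at every duration.

Two further conventions are worth making explicit. First, a person with
any ED history never re-enters the naive-incidence process: all re-onsets
flow through the relapse hazard, and the type of a relapse is the most
recent ED (crossover updates that type, remission does not reset it to
anything else). Data to identify cross-type *naive* incidence after a
first episode do not exist in the calibration targets, and routing all
recurrence through relapse keeps the "risk concentrates in affected
individuals" mechanism in a single parameter family. Second, the relapse
clock resets on every remission to healthy; a crossover within an episode
does not touch it.

### Episodes

An *overall episode* is a maximal contiguous run of ages spent in any ED
state — diagnostic crossover continues an episode, remission ends it. A
*per-ED episode* is a maximal contiguous run in one specific state, so an
AN→OSFED→healthy history contributes one overall episode, one AN episode
and one OSFED episode. This matches how per-person episode counts and
per-disorder recurrence are usually read from annual state sequences.

## Randomness and counterfactuals

Every decision consumes a uniform draw keyed by (master seed, person, age,
decision channel) through a counter-based hash, with five channels: death,
incidence/relapse, ED-type pick, treatment assignment, and
remission/crossover outcome. Because draws are keyed rather than
sequential, scenarios share *common random numbers*: toggling treatment or
zeroing incidence perturbs only the decisions that differ, so persons who
never enter an ED state have bit-identical histories across scenarios and
scenario contrasts (deaths averted) are paired at the person level. The
four standard scenarios are baseline (current treatment), no treatment,
full treatment, and no incidence (prevention of all ED cases).

## Calibration

Free parameters are fitted to prevalence targets by restart simulated
annealing on the loss

$$\mathrm{GOF} = \sum_i \frac{1}{\mathrm{SE}_i}\,(t_i - \hat t_i)^2,$$

the quadratic distance weighted by the *inverse standard error* of each
target (an inverse-variance $1/\mathrm{SE}^2$ weighting is available as an
option). Each search starts from a uniform draw within the prior search
bounds; if a draw implies per-cycle probabilities summing above 1, the
lower bounds of the implicated parameters are multiplicatively lowered
(×0.9 per pass) until a valid set is drawn — a multiplicative shrink keeps
lower bounds nonnegative. Proposals jitter a random subset of free
parameters uniformly within ±5% of each bound width, clipped to the
bounds; a proposal that lands invalid is repaired by halving the jitter
toward the (valid) current point. Uphill moves are accepted with
probability $e^{-\Delta/T}$ under geometric cooling; the initial
temperature defaults to each search's initial score and the cooling factor
defaults to $10^{-4/n_{\text{iter}}}$ so the temperature falls four orders
of magnitude over a search and the late phase is effectively greedy,
whatever the iteration budget. Objective evaluations within a search share
a fixed evaluation seed (common random numbers across iterations), so each
search minimises one fixed realisation of the stochastic loss surface.

The best `keep_k` sets across searches form the calibrated ensemble;
parameter summaries are ensemble means with 95% uncertainty intervals
taken as the empirical 2.5th/97.5th percentiles. Outcome ensembles
re-sample parameter sets from the kept ensemble (uniformly, with
replacement) for each of `nsim` simulation runs, so reported intervals
carry both stochastic (first-order) and parameter (second-order)
uncertainty.

Three annealing profiles are shipped: `paper` (10 000 searches × 1000
iterations, 100 000-person evaluations, keep 100) mirrors the full
published design; `desk` (200 × 500, 20 000-person evaluations, keep 100)
is the scale used by this package's own reproduction pipeline and tests;
`test` is a minutes-scale profile for examples. The desk problem sizes —
20 000-person evaluation cohorts, 100-run × 20 000-person outcome
ensembles — were chosen so that Monte-Carlo error on the target statistics
(≈0.3–0.4 percentage points per evaluation) sits comfortably below the
target standard errors, while a full calibration stays a
single-workstation job.

### What the shipped targets are (and are not)

The survey-by-survey calibration targets used in the original study are
not published numerically. The shipped default target set
(`read_targets()`) therefore uses the four published headline anchors:
annual ANY-ED prevalence at age 21 (7.4% male, 10.3% female) and lifetime
ANY-ED prevalence by age 40 (14.3% male, 19.7% female), with standard
errors back-derived from the published 95% uncertainty intervals as
width/3.92. Users calibrating to their own survey data should supply a
targets CSV (`kind, ed, sex, age_lo, age_hi, value, se`) instead; the
published fit statistic (87% of targets within their confidence intervals)
cannot be reproduced without the original target list and is not attempted
here.

Relatedly, the published table reports a few calibrated means slightly
above their stated prior bounds (e.g. BED male remission 16.3% against a
0–10% bound). The shipped fixture stores both faithfully; the sampler
always respects the printed bounds, while parameter sets built from the
printed means use them as printed (they still satisfy the probability-sum
constraints).

## Incidence curves: one multiplier per disorder and sex

The calibration treats the *age shape* of naive incidence as fixed and
fits one scalar level multiplier per (ED, sex) — eight calibrated scalars.
This keeps the search space small and mirrors the original design, where
age-specific incidence was imputed from published incidence-by-age curves
and only levels were effectively free. `calibrate_multiplier_to_cumulative()`
provides the complementary closed-form anchor: given a shape and a
published multi-year cumulative incidence (for instance an 8-year
cumulative incidence over an adolescent window), it solves
$1-\prod_a (1 - m\,g(a)) = \text{target}$ for $m$ by root-finding, refusing
targets that would push any annual probability above 1.

The multiplier search bounds are not published ("age- and sex-specific").
The shipped bounds encode the relative disorder mix implied by the
published sources — OSFED dominant (its source anchor is an 8-year
cumulative incidence of 24.2% in females, against 2.6% for BED), AN and BN
small — with generous headroom above the levels needed to reach the
published prevalence: upper bounds of 0.003/0.005/0.010/0.028 (male) and
0.006/0.008/0.012/0.035 (female) for AN/BN/BED/OSFED, all lower bounds 0.

## Synthetic structural inputs

Two structural inputs are external data in the original study and are
generated synthetically here (any CSV with the same layout can replace
them):

* **Life table** — Gompertz–Makeham,
  $q(a) = c + A e^{Ba}$, female, with a rate-scale male multiplier.
  Defaults ($c=10^{-4}$, $A=7.8\times10^{-5}$, $B=0.075$, male ×1.75) give
  cumulative mortality to age 40 of ≈2.3% (female) and ≈4.0% (male),
  matching US life-table levels; the generator refuses parameters that
  push any annual probability past 0.02 before age 40. A Gompertz–Makeham
  form cannot reproduce the infant-mortality spike at age 0; ED dynamics
  start years later, so this has no visible effect on any reported
  statistic.
* **Incidence shapes** — Gaussian in log-age (hence symmetric on the
  log-age axis around the peak), peak normalised to 1. Defaults peak at
  ages 16 (AN), 18 (BN), 19 (BED) and 17 (OSFED) with log-widths
  0.17–0.19, placing 94–99% of each shape's mass at or before age 25 —
  the adolescent concentration the imputed curves represent.

The target generator simulates a large cohort under a known parameter set,
reads off each designed target, and adds binomial sampling noise at a
per-target survey size, with $\mathrm{SE}=\sqrt{p(1-p)/n}$ — emulating
survey-derived targets. What the synthetic inputs deliberately do *not*
emulate: survey design effects (clustering, weighting), secular trends,
and covariate-dependent risks. Tests passing on synthetic inputs therefore
demonstrate that the machinery — transition arithmetic, calibration,
uncertainty propagation — is correct under the stated model, not that the
shipped defaults describe any particular real population.

## The parameter-recovery experiment

`recovery_experiment()` closes the loop: sample a ground truth from the
search bounds, generate noisy targets from it, calibrate, and compare the
ensemble-mean fitted prevalence statistics with the noise-free truth as
standardized deviations $z = (\hat t - t_{\text{true}})/\mathrm{SE}$.

Its default design frees only the eight incidence multipliers (all other
parameters pinned at their known values) against twenty-six targets that
mirror the structure of the emulated calibration — per sex, 12-month
prevalence of AN, BN and BED at ages 16/21/26, lifetime OSFED at 20, and
lifetime AN/BN/BED at 35 — at survey size 2000 (an effective sample size
typical of sex-specific survey cells after design effects). Observing each
disorder separately matters: annual AN prevalence has a floor set by
diagnostic crossover *into* AN from the other disorders, so a target set
that observes only aggregate ANY-ED prevalence leaves the BN/BED/OSFED mix
— and with it that floor — unidentified, and the experiment can flag
spurious deviations at auxiliary targets. The rationale: a recovery run in which every parameter is
free can *interpolate* the noisy targets, so its deviation from truth is
simply the target noise and the experiment measures the luck of the noise
draw rather than the optimizer. With eight free scalars facing twenty-six
targets the fit is over-determined, noise is averaged rather than chased,
and a deviation beyond 2 SE indicates a genuine optimizer or model defect.
This mirrors how the calibration is actually deployed in the package's
reproduction pipeline, where only the multipliers are free.

## Numerical choices and degenerate inputs

* Probability transforms use the exact rate-scale forms
  $1-(1-p)^{k}$ throughout; no small-rate approximations.
* The multiplier root-finder brackets on $[0, 1/\max g]$ and converges to
  $10^{-10}$ on the cumulative scale; a window in which the shape is
  identically zero, or a target requiring $m\,g > 1$, is an error.
* Ensemble percentiles use linear interpolation (R quantile type 7).
* Ties in ensemble selection are broken by search seed, so the kept
  ensemble is reproducible even with duplicated scores.
* Degenerate search bounds (`lower == upper`) pin a parameter exactly:
  sampling returns the value, proposals leave it untouched. This is the
  mechanism behind `fix_bounds()` and partial calibration.
* Cohort sizes must be even (exact 50/50 sex split); the deceased state is
  structurally absorbing (the engine writes the remaining ages in one
  pass).

## Known limitations

The model inherits the original design's scope: a closed birth cohort to
age 40 with annual cycles (no within-year dynamics, no secular trends, no
open-population entry), no ARFID state, no covariate-dependent risks, and
treatment acting on remission only — no effect on relapse or mortality.
Lifetime prevalence is reported as cumulative incidence over the full
birth cohort by default (deaths stay in the denominator, so the curve is
nondecreasing); the survivor-conditioned variant, which is what
cross-sectional surveys measure and is used when matching survey-based
calibration targets, is available via `surviving_only = TRUE`. By age 40
the two differ by well under one relative percent. Whether the original
lifetime curves condition on survival is not stated; the difference is far
inside every reported uncertainty interval.
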