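---
title: "A dynamic multi-state model of disability and cognitive impairment in an aging population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dynamic multi-state model of disability and cognitive impairment in an aging population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`mspop` projects the number of older adults living with functional
disability and cognitive impairment over a 50-year horizon (2010--2060)
with a deterministic cohort-component multi-state model. The population
aged 65+ is partitioned into 12 living health states -- the product of four
cognitive categories (MMSE >= 24 intact; 18--23 mild; 10--17 moderate;
<= 9 severe) and three functional categories (0 ADL limitations; 1--2; 3+,
out of six basic activities of daily living) -- plus an absorbing death
state. Each state is further resolved by single year of age (65--100,
with 100+ an open interval) and sex.

A feeder population aged 0--64 supplies new 65-year-olds: it gains births
(female stocks aged 15--49 times age-specific fertility rates) and net
migrants, loses deaths (life-table probabilities), and its survivors of
age 64 enter the 65+ system -- by assumption in the intact-active state.
Each simulated year then runs, in this order: births, sub-65 survival and
aging, 65+ health-state transitions, 65+ age shift (100+ accumulates),
entry at 65.

Within a year, 65+ transitions are the composition of two kernels:

* a **cognitive kernel**: annual transition probabilities between the four
  cognitive categories and death, by age and sex;
* a **functional kernel**: annual transition probabilities between the
  three functional categories and death, by age, sex, and a binary
  cognitive-impairment (CI) stratum.

The cognitive kernel is applied first; the functional kernel then uses the
CI stratum of the *post-update* cognition. This ordering is the model's
central mechanism -- cognitive decline raises the probability of disability
onset in the same year. The reverse order is available
(`project(..., cognitive_first = FALSE)`) as a sensitivity analysis.
Because the two kernels are estimated in separate models that both contain
a death outcome, the combined annual death probability is the
competing-risks product `1 - (1 - p_death_cog)(1 - p_death_fun)`; no
de-duplication of the two death risks is attempted, which will slightly
overstate mortality if the same underlying deaths inform both models. This
is a documented modelling choice, not an estimate.

### Assumption schedules

Three schedules (all tunable via `assumption_schedule()`):

* **Fertility freeze**: calendar-year fertility schedules are used through
  2017 and frozen at the 2017 schedule afterwards -- fertility after 2017
  cannot affect the 65+ population before 2082 anyway.
* **Mortality decline**: sub-65 death probabilities fall by 1.5% per year
  (factor `(1 - 0.015)^(year - 2010)`). The decline applies to the sub-65
  life table only; 65+ mortality sits inside the transition kernels and is
  improved by the transition-improvement schedule instead. Applying both to
  the same flow would double-count improvement.
* **Transition improvement**: every worsening and death probability in the
  65+ kernels is multiplied by `(1 - 0.01)^(year - 2014)`, the freed mass
  being added to the stay probability (recovery probabilities are left
  unchanged, so rows still sum to one and no-recovery constraints are
  preserved). The base year 2014 is the end of the estimation window;
  earlier years are unadjusted.

## Estimating the kernels from a two-wave panel

The input is a two-wave survey (two years apart) of adults 65+: composite
health state at each wave, vital status at wave 2, age, sex, and a
sampling weight. Two-year observations are converted to annual transitions
by **midpoint imputation**: a respondent in the same category at both
waves is assumed to have been in it at the midpoint year; a respondent in
different categories (death included) is assigned the wave-1 or wave-2
value with equal probability -- the maximum-entropy reading of "the
transition happened at random in one of the two years". Each respondent
then contributes up to two one-year transition pairs (both enter the
likelihood; the dependence between a respondent's two pairs is ignored in
point estimation and carried into the intervals by resampling whole
respondents in the bootstrap).

Per origin state `i`, destination probabilities follow a multinomial logit
with "stay" as reference:

* cognitive: `ln(p_ij / p_ii) = b0 + b1 age + b2 age^2 + b3 sex`
* functional: `ln(p_ij / p_ii) = b0 + b1 age + b2 sex + b3 CI`

with sex coded female = 1 and CI = 1 for any cognitive impairment. The
choice set excludes structurally forbidden destinations (no recovery from
moderate or severe CI; none from 3+ ADL limitations), so forbidden cells
are exact zeros by construction rather than zeroed after the fact.

Design choices worth knowing:

* **Age centring.** Age enters as `age - 80` (and its square). Over the
  65--100 range an uncentred quadratic is numerically ill-conditioned, and
  back-transforming inflates the age-squared sampling error by a factor
  80^2 into the intercept; coefficients are therefore stored and compared
  on the centred scale, with `coef_natural()` providing the uncentred view
  for reporting.
* **CI covariate timing.** For the functional model the CI indicator is
  the cognition at the *end* of each one-year interval (the imputed
  midpoint cognition for the first pair, the wave-2 cognition for the
  second; the last known cognition when the interval ends in death). This
  matches the projection, which applies the functional kernel to the
  post-cognitive-update stock, so estimation and simulation describe the
  same mechanism.
* **Solver.** The per-origin weighted multinomial logits are fitted by a
  small Newton solver with the exact Fisher information, warm-started at
  the empirical log-odds (or at the point estimate when refitting
  bootstrap replicates) with step-halving. Convergence is declared when
  the score vanishes or a full Newton step falls below 1e-9. The problem
  is concave and at most 16-dimensional, so this is fast and exact;
  `nnet::multinom` on the same data is used as an independent cross-check
  in the test suite, never as the implementation.
* **Degenerate cells.** A permitted destination never observed in the data
  gets its intercept fixed at -20 (probability ~ 2e-9) with a warning. True
  non-convergence or complete separation (possible in small resamples,
  where a rare destination may have a handful of events perfectly
  separated by age) raises a classed error advising more data; the
  bootstrap re-draws such replicates with a shifted seed and aborts if
  more than 5% of replicates need it.
* **Ages above 100** use the age-100 kernel row (open interval); pair ages
  are capped at 100 on entry.
* **Lost to follow-up** (no wave-2 state, not recorded dead): dropped with
  a logged count; the method has no information about them.

The midpoint imputation is an approximation, not an unbiased estimator of
the annual kernel: when transitions are frequent, imputed exposure is
systematically attributed to the wrong state often enough to attenuate
age slopes and shift intercepts (a two-state worked example: with true
annual transition probability p, the imputed event/exposure ratio is
`p(2-p) / (2(1-p)^2 + 1.5 p(2-p))`, which is slightly below p for
moderate p and increasingly below it as p grows). The package therefore
separates two validation questions: the *regression machinery* is
validated against ground truth using complete-interval pairs
(`midpoint = "recorded"`, available from the synthetic generator's debug
flag), while the *end-to-end two-wave method* -- imputation included -- is
exercised by the pipeline and structural tests, where the estimand is the
method's own probability limit rather than the generating kernel.

## Bootstrap uncertainty

Following the survey-bootstrap design: sampling weights are rescaled to
sum to one and used as draw probabilities; each replicate draws n
respondents with replacement (a respondent may appear any number of
times), carries unit weights (the design weights were consumed by the draw
probabilities; weighting the replicates again would double-count), and is
pushed through the full estimation, midpoint imputation included.
Replicate r uses seed `base_seed + r`, so the stream is reproducible and
independent of weight rescaling. Intervals are percentile intervals: the
order statistics at ranks `floor((B+1) * 0.025)` and
`ceiling((B+1) * 0.975)` of the B replicate values of each quantity.
Intervals for projected counts are obtained by running the projection once
per replicate kernel set and taking percentiles of each output cell.

## The synthetic cohort

Because the source survey and census inputs are restricted, every
validation runs on synthetic data with known ground truth:

* `truth_presets()` ships five kernel sets: `null` (no transitions),
  `paper_like` (worsening and death log-odds increase with age and CI,
  recovery decreases with age; female excess for cognitive onset and for
  mild-CI recovery/death and severe-CI death, male excess for ADL
  progression and most other deaths), `stress` (high turnover), and the
  single-process variants `cognitive_only` / `functional_only` used for
  calibration experiments (one process active, the other frozen, so the
  marginal estimand equals the kernel truth -- with both processes active,
  observed deaths are shared between the two marginal models and neither
  model's death equations estimate its own kernel).
* `generate_survey()` draws a wave-1 composite state from a stated
  mixture, then simulates two sequential annual transitions with the truth
  kernels in the projection's combination order, recording only the
  wave-1/wave-2 states (the midpoint stays hidden unless
  `keep_midpoint = TRUE`).
* `generate_demographics()` builds a deterministic, schema-complete set of
  demographic inputs from a handful of scenario parameters.

Deliberate generator choices (fixed once, documented here):

* The wave-1 state mixture is severity-enriched (cognition
  38/26/20/16%, function 47/31/22%) relative to community prevalence so
  that every origin state carries enough exposure for stable estimation;
  the generator aims for structural, not empirical, realism, and no
  attempt is made to match real survey marginals.
* Wave-1 ages are near-uniform over 65--100 (geometric decay 0.02/year),
  mirroring the deliberate oversampling of the oldest old in longevity
  surveys and giving the age-quadratic real support at high ages.
* The sex mix is 1010 female : 814 male, the composition of the source
  panel; weights are log-normal (sdlog 0.5) to exercise the
  rescaling/resampling path, with a unit-weight option for clean recovery
  experiments.
* The demographic scenario defaults describe a large aging population of
  1.34 billion with roughly 10% aged 65+, TFR 1.65 declining 1%/year over
  2010--2017, Gompertz-Makeham sub-65 mortality with a 15% male excess,
  sex ratio at birth 1.05 (configurable; the source model does not state
  one), zero migration (the source names migration but gives no values;
  when supplied it applies to sub-65 ages only), and a mildly impaired
  initial 65+ state mixture (80% intact-active). The initial 65+
  allocation across health states is a required modelling input the source
  does not specify; `demographic_inputs()` defaults to all intact-active
  unless a prevalence vector is given.

What passing tests on these data do **not** show: that the fitted kernels
describe any real population (the presets are stylized), that the
imputation approximation is negligible at real-world transition rates, or
that projections at the published scale are reproduced (that would require
the restricted microdata and official demographic inputs).

## Validation design and problem sizes

* **Parameter recovery** (test suite): five independent surveys of
  n = 20,000 per single-process preset, complete-interval pairs; the five
  coefficient fits are averaged before comparing with truth at a +-0.1
  tolerance, and the implied probabilities at ages 70/80/90 at +-0.02. The
  averaging is an a-priori power decision: the rarest origin-destination
  cells (e.g. the sex coefficient of the severe-CI death equation, with
  ~6,000 pairs and p*q ~ 0.2) have per-survey standard errors near 0.05,
  so a single-survey +-0.1 check would sit at ~2 sigma and fail by chance
  a substantial fraction of the time, telling us nothing about
  correctness; the 5-survey mean brings the worst-case error to ~4.5
  sigma of the tolerance.
* **Bootstrap coverage**: 100 simulated surveys (n = 2,000) from the
  `cognitive_only` preset, 200 replicates each (a deliberate scale-down
  of the production 1,000), pooled coverage of the true cognitive
  probabilities at ages 70/80/90 across sexes, origins and destinations,
  required to land in [90%, 99%]. One process is exercised; the
  resampling/refitting machinery is identical for the other.
* **Projection equivalence**: the full 2010--2060 run on a 1e6-person
  scenario is compared cell-by-cell (tolerance 1e-9 persons) against an
  independent scalar nested-loop re-implementation kept in the test
  helpers, and a frozen-cognition constant-kernel toy is compared with the
  matrix-power closed form over 30 years.
* **Structure**: conservation (total(t+1) = total(t) + births - deaths +
  migration) to 1e-9 persons at the 1e6 scale (the identity is
  scale-invariant; at a 1.34e9-person scale the double-precision floor of
  summing the stocks is itself above 1e-9 persons), row sums to 1e-12,
  structural zeros exact before and after the improvement adjustment,
  non-negativity, and the monotone effect of the improvement rate.

## Limitations

* The two-wave midpoint imputation is the published method and is kept
  faithfully, including its attenuation bias at high transition rates.
* The two death outcomes are combined as independent competing risks; the
  model cannot identify their overlap from marginal fits.
* Entrants at 65 are assumed intact and active, understating impairment
  at ages 65--66.
* Fractional persons (expected-value dynamics) -- no demographic
  stochasticity; uncertainty comes solely from the transition-rate
  bootstrap, not from fertility/mortality inputs.
* Covariates are limited to age, age^2, sex and CI; no cohort, period,
  education or urban/rural effects.
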