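---
title: "Modeling presymptomatic AD screen-and-treat strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling presymptomatic AD screen-and-treat strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

adscreensim is an individual-level Monte Carlo microsimulation of
presymptomatic Alzheimer disease (AD) screening and treatment. It asks a
population-level question: under what combinations of screening accuracy,
treatment efficacy, treatment harm and adherence does a screen-and-treat
program deliver net quality-adjusted life years (QALYs) to a cohort of
older adults who do not yet have AD? This vignette is the package's own
account of the model: its structure, its assumptions, the numerical
choices, and what the simulations can and cannot show.

## The life-history cohort

A cohort of `population_size` individuals (default one million) shares a
single base age (55–75 in five-year steps). Each individual receives:

* a **sex**, Bernoulli in the base-age-specific proportion female from a
  census-style table;
* a **non-AD death age**, sampled by walking the sex-specific life table
  one year at a time from the base age: in each year the individual dies
  if a fresh uniform draw falls below the annual death probability `q` for
  that age and sex. The life table must end in a terminal age with
  `q = 1`; the model also enforces a hard cap at age 120. The shipped
  life table is a synthetic Gompertz approximation to US mortality (see
  `inst/extdata/PROVENANCE.md`), so absolute survival is realistic but
  not a transcription of any official table;
* a **risk score**, uniform on (0, 1), which encodes the individual's
  conversion priority, and an **AD onset age** derived from it as follows.

Annual AD incidence follows an exponential curve anchored at age 60
(default 0.00117/year, doubling every ~5.5 years) with a halving per five
years of age below 60. Each year, the incidence rate times the count of
not-yet-converted members of the *original* cohort — alive or dead —
yields that year's conversion quota (rounded to the nearest integer, with
the fractional remainder carried forward so long-run totals are
unbiased). The quota is filled by the not-yet-converted individuals with
the highest risk scores, ties broken by id. Conversions assigned at or
after the individual's death age are recorded but *censored*: they are
never expressed, contribute nothing to outcomes, and cannot be prevented.
This "original cohort" denominator keeps the population incidence curve
calibrated; a stricter alive-only risk set is available via
`risk_set = "alive"`. Within a year the order of events is fixed: death
check first, then onset check, so an onset in the death year is censored.

Under this construction nearly every individual is eventually *assigned*
an onset age (late-life incidence is large), while the fraction who
*express* AD before dying — about a fifth of a 55-year-old cohort — is
what a realistic lifetime risk looks like. Both quantities matter: the
assigned destiny drives screening classification, the expressed onset
drives outcomes.

## The AD course: an annual-cycle Markov model

An individual who expresses AD enters a severity-by-location Markov model
with annual cycles. Initial severity is mild with probability 0.6 and
moderate with 0.4. Each subsequent year applies, in order: a severity
transition (stay, worsen by one or two levels, or die — severities never
improve); if death, the path ends and the year accrues nothing; otherwise
a location transition (community to nursing home with a severity-specific
probability; the nursing home is absorbing); then utility accrual at the
*new* state. The onset year itself accrues utility at the initial
severity, in the community — the printed transition table gives no
initial location, so community start is the package's choice. The printed
moderate-severity row sums to 0.957; rows are renormalized
proportionally at load (with a message), the least-informative repair.

Mortality with AD depends on severity only. The printed utilities cover
each severity-location pair (0.37/0.52, 0.18/0.21, 0.02/0) and non-AD
years take age-band utilities (0.872, 0.836, 0.809, 0.775 for 55–64,
65–74, 75–84, 85+). All utilities are discounted from the *base age* with
the convention `(1 - rate)^years` at 3%/year — note this is not the usual
`1/(1+r)^t`; the year of age 90 for a 55-year-old is weighted 0.34.
Accrual is annual with no half-cycle correction, matching the discrete
yearly model.

## Screening

A single screen at the base age predicts conversion within a 20-year
horizon (inclusive: onset exactly 20 years out counts). Horizon
converters screen positive with probability `sensitivity` (0.65), others
with `1 - specificity` (0.95), giving TP/FN/FP/TN labels. By default the
converter status is the *assigned* onset destiny regardless of later
censoring (`count_censored = TRUE`): the screen is defined by the
pre-test, population-average 20-year risk, which is the Brookmeyer-type
cumulative incidence, not the survival-censored risk. This choice is
load-bearing — at base age 75 roughly half the cohort is an assigned
20-year converter while far fewer live to express it, and only the
assigned definition reproduces the published count of ~370 treated per
1000 screened. The censored alternative is one switch away.

A consequence worth understanding: a "false positive" who converts in
year 25 is a real future AD case outside the screen's horizon. Such
individuals are treated and can benefit, which is why false positives as
a group can show small net *gains* at younger base ages.

## Treatment

Treated individuals (screen-positives, or everyone under `treat_all`)
start therapy at the base age. Three treatment parameters shape benefit
and two shape harm:

* **RRR slope and ceiling.** The relative risk reduction for a destined
  onset `L` years after initiation is `min(slope * L, ceiling)` — earlier
  treatment is more effective, up to a ceiling (defaults 0.03/year and
  0.5; the ceiling binds from 17 years of lead time). An individual still
  on treatment at their destined onset year has the onset suppressed with
  this probability.
* **Harm.** Each treated year carries a `harm_prob` (0.001) chance of a
  one-time `harm_magnitude` (0.06) QALY decrement, discounted at the year
  it occurs; harm stops treatment permanently.
* **Discontinuation.** Each treated year carries an independent
  `discontinuation_rate` (0.05) chance of stopping for non-harm reasons,
  with no decrement. Harm is checked before discontinuation within a
  year.

The annual harm and discontinuation Bernoulli sequences are realized by
inverse-CDF geometric sampling from one uniform per individual — exactly
the same distribution as year-by-year draws, but comonotone in the rates,
so paired-seed sensitivity curves are pathwise monotone rather than
monotone only in expectation.

### What does a suppressed onset mean afterwards?

This is the one genuinely open structural question in the model, and the
package implements three answers behind `benefit_model`:

* `"masked"` (default): disease *expression* is averted only while
  treatment continues. Every year of the individual's AD course that
  falls before their treatment stop accrues the non-AD age-band utility
  instead of the AD utility; the course underneath, including its
  mortality, is unchanged, and stopping treatment drops the individual
  back into it. Benefits therefore require long-term treatment, and
  population survival is identical across strategies.
* `"on_treatment"`: suppression prevents the disease itself while
  treatment lasts; the individual follows life-table mortality, and a
  later stop lapses into a delayed onset with a fresh Markov course.
* `"permanent"`: suppression at the destined onset year cancels the
  onset for good.

The default was chosen by model-structure identification against the
published aggregate results rather than by taste: only the masked reading
reproduces, simultaneously, the per-screened and per-treated net QALYs
within ±20% at every base age, the exact age-orderings (benefit per 1000
screened rising with age, benefit per 1000 treated falling from 60 to
75, treat-all benefit per treated rising with age), and the small
positive net utility in false positives — and it is the only reading
under which simulated survival curves match the life table in every
scenario, as the source model's validation requires. The permanent
reading overshoots net benefit by up to ~90% at younger ages; the
delayed-relapse reading by ~30%, with inverted age gradients at the top
of the range. A caveat follows honestly from the masked structure: a
suppressed individual who dies "AD-free" still dies on the AD course's
schedule, so the treatment modeled here buys quality of life, not
longevity. Users who want prevention to extend life should switch to
`"on_treatment"` and expect systematically larger net benefits.

Untreated and treated worlds use common random numbers throughout: the
cohort, the AD paths and the treatment draws are derived from per-purpose
substreams of one run seed, so everything treatment does not touch
cancels exactly in the per-individual net utility, and comparing
strategies never perturbs the underlying histories.

## The trial engine

`run_simulation()` samples `n_trials` (1000) trials of `trial_size`
(1000) individuals without replacement from the cohort, sums the
per-individual net utilities of those the strategy treats, and reports
the mean per 1000 screened, per 1000 treated (the exact algebraic ratio),
counts of treated and false positives, the false-positive net utility,
and the spread across trials. `prevalence_curve()` reproduces the
flat-RRR, treat-all, no-discontinuation validation scenario: AD
prevalence among survivors with and without treatment.

## Sensitivity analyses

* **One-way** (`one_way_sensitivity()`): any intervention or diagnostic
  parameter, the discount rate, or the base age over a grid, all else at
  base case, with the same seed at every grid point.
* **Two-way** (`two_way_harm()`): the harm probability x magnitude grid.
* **Probabilistic / third-order** (`run_psa()`): all parameters drawn per
  iteration — intervention and diagnostic parameters uniform over their
  one-way ranges, non-AD utilities uniform over their published ranges,
  AD utilities additively perturbed by ±0.1 (clamped to [0, 1]),
  initial-severity, transition and nursing-home probabilities perturbed
  by ±10% relative with rows renormalized. The life-history layer
  (mortality, incidence) carries no sampled uncertainty, so the cohort is
  built once and reused. Each iteration reports net benefit, a
  beneficial flag (net > 0), total harm (`harm_prob * harm_magnitude`),
  and three auditable efficacy summaries: the realized mean RRR across
  treated individuals with an assigned onset, the raw slope and ceiling
  draws, and slope x mean lead time. `summarize_psa()` produces the
  group-mean comparison by beneficial flag, total-harm quantiles among
  beneficial iterations, and the benefit-quintile x total-harm table.

One structural property is worth flagging: under the masked benefit
model, treatment benefit is non-negative (non-AD utilities always exceed
AD utilities), so an iteration with negligible harm can be beneficial at
low efficacy. The beneficial/non-beneficial contrast in mean efficacy is
still clearly present in the packaged PSA runs — low total harm is
simply a stronger requirement than high efficacy, and higher efficacy
widens the harm budget an iteration can absorb — but it is somewhat
attenuated relative to a model in which weak treatment can net out
negative on its own (the `"on_treatment"` reading, where a lapsed
suppression becomes a delayed onset).

## Numerical and design choices

* Ages are integer years; one-year cycles; age cap 120 with forced death.
* Quota rounding: round-to-nearest with carried remainder (unbiased).
* Risk-score ties broken by id; all tie-breaks deterministic.
* Substream seeds: cohort build (1), AD paths (2), classification (3),
  treatment draws (4), trial sampling (5), PSA parameter draws (6),
  prevalence (7), relapse courses (8); all derived from the run seed with
  integer arithmetic kept below 2^53.
* Degenerate inputs are validated at construction: transition rows
  renormalize, probabilities and utilities are range-checked, life tables
  must be contiguous with a terminal `q = 1`.
* Default problem sizes: the full study design is a 10^6-person cohort
  with 1000x1000 trials per (age, strategy); the packaged tests run that
  design for the calibration and base-case checks, a 10^5 cohort with 200
  trials for sensitivity grids, and 2000 PSA iterations on a 2x10^4
  cohort with 100 trials each, sizes at which Monte Carlo error is well
  inside the tolerances being asserted. The full 10,000-iteration PSA is
  one argument away.

## What the synthetic data can and cannot show

Every test runs on data the package generates: either the shipped
synthetic calibration fixtures or the `make_toy_fixtures()` generator
(Gompertz-like toy life tables, toy incidence curves). Passing tests
therefore demonstrate internal correctness — calibration of the cohort
machinery to its own inputs, agreement of sampled Markov courses with
closed forms, the algebra and orderings of the published aggregate
results — under mortality and incidence inputs that *approximate* US
data. They do not demonstrate that any specific treatment works, nor
calibrate absolute QALY totals to a real cohort; the absolute incidence
level in particular inherits the uncertainty of the unprinted incidence
coefficients, which moves per-screened benefits at younger base ages by
roughly the size of that uncertainty.

## Known limitations

* No risk-factor covariates (education, vascular risk, comorbidity);
  the model targets population averages, not subgroups.
* No repeat screening, no re-initiation after discontinuation, no dose
  or adherence gradation, no treatment effect on progression speed.
* No costs: outcomes are QALYs only, so this is a benefit-harm model,
  not a cost-effectiveness analysis.
* AD mortality is severity-specific but age-independent, so very old
  onsets carry implausibly long courses; the masked benefit model makes
  results insensitive to this, other benefit models less so.
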