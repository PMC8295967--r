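---
title: "Distributional cost-effectiveness of smoking cessation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributional cost-effectiveness of smoking cessation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dceasmoke)
```

## The decision problem

Two smoking-cessation interventions delivered through primary care —
varenicline and a 7.2 mg e-cigarette — are compared with each other and
with no intervention, for the adult smoking population of England (and
two local authorities, York and Sheffield), from an NHS and personal
social services perspective over remaining lifetime.  A distributional
cost-effectiveness analysis (DCEA) tracks outcomes separately for the
five deprivation quintiles of the Index of Multiple Deprivation (IMD1 =
most deprived) and summarises each pairwise comparison on two axes:

* **Overall health**: population incremental net health benefit,
  $\mathrm{iNHB} = \sum_q \Delta\mathrm{QALY}_q - \frac{s_q \sum_q \Delta C_q}{k}$,
  where total incremental cost is pooled, converted to forgone health at
  the threshold $k$ = £20,000/QALY, and distributed across quintiles by
  opportunity-cost shares $s_q$ that fall more heavily on deprived
  quintiles.
* **Health inequality**: the inequality impact
  $\mathrm{iEDE} - \mathrm{iNHB}$, where iEDE is the population change in
  Atkinson equally-distributed-equivalent (EDE) health after adding each
  quintile's per-person share of iNHB to its baseline quality-adjusted
  life expectancy (QALE).  A positive value means the intervention
  narrows the health gap.

Uncertainty analysis asks how confident one can be on each axis
(probabilistic sensitivity analysis, PSA), what resolving the
uncertainty would be worth (EVPI/EVPPI), and which parameter groups
drive it (ANCOVA).

## The cohort model

Each quintile's smokers are simulated with a three-state annual-cycle
Markov cohort model: *smoker*, *former smoker*, *dead*.  The whole
cohort enters as smokers, uniformly across entry ages 18–75.  In the
first cycle of an active arm, a smoker quits with the intervention's
12-month quit rate times the quintile's relative risk of quitting
(IMD1 is the reference); in every other cycle — and in all cycles of the
no-intervention arm — the background quit rate of 2%/year applies, with
the same relative risk.  There is no relapse.  Intervention unit costs
are charged in the first cycle only, and only to smokers who take the
service up (uptake rates differ by quintile).

Mortality by smoking status is decomposed from all-cause mortality so
the status-weighted average reproduces the all-cause rate:

$$m_s = \frac{m_{\text{all}}}{p_s + p_f / RR_{svf} + p_n / RR_{svn}},
  \qquad m_f = m_s / RR_{svf},$$

with $RR_{svn}$ (smokers v. nonsmokers) age-banded and $RR_{svf}$
(smokers v. former smokers) constant across ages.  The published bands
start at 35–44; entrants younger than 35 use the 35–44 value.  With
relative risks above one this makes smokers die faster than the
population average, as they must.

Six smoking-related diseases (lung cancer, coronary heart disease,
COPD, myocardial infarction, stroke, asthma exacerbation) are modelled
as independent memoryless events: expected counts per cycle are
occupancy × incidence(age, status) × a quintile relative risk, and each
event carries a one-cycle cost and utility decrement.  Base incidence is
taken to represent IMD3, so quintile relative risks are rescaled by the
IMD3 risk (`disease_rr_mode = "imd3_normalised"`; a raw mode is
available).  Utilities come from a linear HRQoL regression (constant +
age band + smoker indicator + IMD), whose coefficient vector is drawn
jointly via a Cholesky-type factor of its covariance.

Timing conventions: transitions are quit-then-die within a cycle;
QALY, cost and event accruals use start-of-cycle occupancy; the
discount factor for cycle $t = 0, 1, \dots$ is $(1+r)^{-t}$ with
$r = 3.5\%$ for both costs and QALYs; there is no half-cycle
correction.  The cohort is censored at age 100.  Sampled utilities can
exceed 1 when the regression constant draws high; values are retained
with a warning, since truncating them would bias the correlated draw.

The production path is vectorised over all 58 entry ages at once;
`run_cohort_trace()` is the explicit single-cohort loop, and the two are
cross-checked to 1e-12 in the tests.

## Parameters and distributions

The national parameter table is shipped verbatim: Beta distributions for
smoking prevalence and uptake, lognormal for all relative risks
(parameterised by the mean `lm` and SD `lv` of the log value),
Beta for the two average quit rates, and a multivariate-normal HRQoL
coefficient block.  Reference levels (relative risk of quitting in IMD1,
of disease in IMD5) are fixed at 1 and never sampled.  Moment-matching
constructors implement the stated rules: `beta_from_mean_se()` for
"standard error = 10% of the mean" uptake rows and for local-authority
prevalence given as mean with a 95% CI (normal-approximation SE), and
`gamma_from_mean_se()` for costs and disutilities.

The printed table is internally inconsistent in places: the mean column
and the printed $(\alpha, \beta)$ disagree at the last printed digit for
some prevalence and uptake rows.  The fixtures store the printed
$(\alpha, \beta)$ and the tests compare means within 0.02 percentage
points, wide enough to cover the table's own rounding.

Three inputs the model needs are not published and are constructed
synthetically, with the construction documented and flagged:

* **HRQoL coefficient covariance** — built as $DRD$ with SEs of 10% of
  each |coefficient| (floor 0.005) and exchangeable correlation
  $\rho = 0.2$.  Because $D$ is diagonal, $L = D\,\mathrm{chol}(R)'$
  factorises the covariance even when some SEs are exactly zero (used by
  the flat scenario).
* **Costs and disutilities** — order-of-magnitude 2018 GBP placeholders
  (e.g. varenicline course £163, stroke event £10,000) under the stated
  gamma/10% rule.
* **External tables** — see below.

Sampled probabilities are truncated to [0, 1] and relative risks to
(0, ∞) after transformation; truncation events are counted and reported
in the PSA result and run manifest (they do not occur under the shipped
distributions).

## Synthetic external inputs

`generate_external_inputs()` emulates the inputs the analysis takes from
national statistics that are not printed in the source tables: all-cause
mortality by age and quintile (Gompertz-like curve, deprivation
multipliers 1.35–0.80, mild seeded jitter, made monotone in age by a
running maximum); smoking-status proportions by age and quintile
(prevalence gradient scaled by an age profile); disease incidence by age
and status (exponential in age, former smokers at half the smoker
rate); baseline QALE per quintile (62–74 QALYs from IMD1 to IMD5);
opportunity-cost shares (0.30 down to 0.10); and the inequality-aversion
parameter $\varepsilon = 10.95$, which is a placeholder for the
survey-elicited value that is not printed — `run_psa()` and the equity
settings accept an override, and a sweep over
$\varepsilon \in \{0, 1, 2, 5, 10.95, 20\}$ is a one-liner.

These stand-ins preserve the *structure* of the real inputs (directions
and rough magnitudes of the gradients) but not their values, so
absolute population results (e.g. national iNHB in QALYs) are
structurally comparable to, but numerically different from, the
published figures.  What the passing tests do show: the machinery's
closed-form identities, invariants and reproducibility.  What they
cannot show: agreement with results that depend on the unpublished
mortality, incidence, QALE, opportunity-cost and aversion inputs.

Scenarios: `default`; `flat`, which removes every quintile gradient and
— paired with the flat parameter book, where quintile-varying inputs are
fixed at common values rather than drawn independently from identical
distributions — makes the inequality impact identically zero, a strong
end-to-end symmetry check; and `steep_gradient`, which widens the
gradients.

## Equity metrics: numerical design

`atkinson_ede()` implements the standard forms (power mean for
$\varepsilon \ne 1$, geometric mean at $\varepsilon = 1$, arithmetic
mean at $\varepsilon = 0$).  `incremental_ede()`, however, does **not**
subtract two EDE levels: the per-person increments ($\sim 10^{-3}$
QALYs) are twelve orders below baseline QALE once multiplied by a
population of $4\times 10^7$, and the naive difference loses enough
precision to leave artefacts of $\sim 10^{-6}$ QALYs in the inequality
impact.  The EDE difference is instead computed in increment space with
`log1p`/`expm1`, which keeps it accurate at the scale of the increment
and makes the flat-scenario inequality impact vanish to $\sim 10^{-10}$.
The tests compare both routes on moderate inputs.

Population iNHB per quintile is diluted over the whole quintile
population when added to QALE (`dilution = "population"`), which makes
$\varepsilon = 0$ give iEDE = iNHB exactly, so the inequality impact is
a pure inequality signal; a smokers-only dilution mode is exposed for
sensitivity analysis.  Opportunity costs are pooled before distribution
by $s_q$, reflecting displacement of a common budget.

## PSA, VOI and ANCOVA

The PSA draws one joint parameter sample per iteration (common random
inputs across the three arms, so an arm's increment against itself is
exactly zero), with per-iteration seeds spawned from the root seed up
front — results are bitwise reproducible and order-invariant.  The
default is 1,000 iterations, which takes a few minutes on one core;
tests and examples use smaller runs where the property under test
allows.

VOI payoffs are monetised at $k$: the health framing pays
$\{0, k\,\mathrm{iNHB}\}$ for the two arms of a comparison, the equity
framing $\{0, k(\mathrm{iEDE}-\mathrm{iNHB})\}$.  The payoff builder is
deliberately swappable — the published analyses do not spell out the
construction, and population-level payoffs (rather than per-person
payoffs rescaled by population and horizon) are used here, with
`population_scale_monetize()` as the explicit knob.
EVPI is the sample identity
$E[\max_d] - \max_d E$; its estimator is validated against the
unit-normal-loss closed form
$\sigma\phi(\mu/\sigma) - |\mu|\Phi(-|\mu|/\sigma)$ on a toy problem.
EVPPI regresses each decision's payoff on the parameter subset: an
additive smoothing-spline GAM (basis dimension 4 per term) for up to 4
columns, and Gaussian-process regression beyond that.  The GP's noise
variance is anchored to the residual fraction of a pilot additive GAM on
the same columns (floor $10^{-3}$): with its default near-zero nugget
the GP interpolates Monte Carlo noise and EVPPI estimates inflate.
Estimates are clipped into $[0, \mathrm{EVPI}]$, the information
ordering, enforced against the same payoff sample.

ANCOVA standardises the inputs, fits one main-effects linear model on
all grouped columns, and attributes each group's share of the output's
total sum of squares by the marginal (drop-one-group) increment in
explained SS; a sequential mode exists, and the two agree within 2% for
independently sampled inputs.  Whether outputs should also be
standardised does not affect shares (they are ratios of sums of
squares).  Parameter groups mirror the published sensitivity axis:
prevalence, RR of death, RR of disease, HRQoL coefficients, average quit
rates, RR of quitting by IMD, uptake by IMD, costs, disutilities — and
the same grouping feeds the EVPPI report, so the two rankings are
comparable.  Shares are main-effects only; interactions are outside the
linear attribution and show up as residual.

## Problem sizes

Defaults reflect the analysis scripts: 1,000 PSA iterations; 58 entry
ages (18–75, uniform); age cap 100 (~82 cycles); 5 quintiles × 3 arms
per iteration.  The test suite uses 100 randomised draws for the Markov
invariants, $10^5$ draws for the EVPI oracle, 5,000 for the ANCOVA
toy, 200 flat-scenario iterations for the symmetry check, and one full
1,000-iteration PSA run twice for bitwise reproducibility.

## Known limitations

* No relapse, no time-varying intervention effect beyond cycle 1, no
  prevalent-disease states (each event costs once) — all inherited model
  assumptions.
* Mortality is aggregated over sex; the synthetic mortality table is
  age × quintile only.
* Quintile relative risks are drawn independently (no cross-quintile
  correlation), as stated for the source analysis; the smoking-status
  proportions entering the mortality decomposition are fixed externals,
  not sampled.
* Absolute results depend on the synthetic externals and placeholder
  cost table; only their structure, not their values, carries over to
  the real setting.
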