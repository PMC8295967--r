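# dceasmoke

Distributional cost-effectiveness analysis (DCEA) of smoking-cessation
interventions with a full uncertainty-analysis toolchain.

Standard cost-effectiveness analysis asks whether an intervention buys
health at an acceptable price; public-health decision makers also ask
who gets that health. This package implements a DCEA of two
smoking-cessation interventions (varenicline and a 7.2 mg e-cigarette,
each against no intervention and against each other) for the adult
smoking population of England and two local authorities (York,
Sheffield), stratified by deprivation quintile (IMD1 = most deprived …
IMD5 = least deprived). It is aimed at health economists and
public-health analysts who want the machinery — not just the point
estimates — for equity-sensitive decision modelling.

Two statistics summarise each pairwise comparison:

* **Population iNHB** (overall health):
  `iNHB_q = ΔQALY_q − s_q · ΣΔC / k`, with incremental costs pooled and
  converted to forgone health at the threshold k = £20,000/QALY,
  distributed by opportunity-cost shares `s_q`; `iNHB = Σ_q iNHB_q`.
* **Inequality impact** `iEDE − iNHB`: each quintile's iNHB, diluted per
  person, is added to its baseline quality-adjusted life expectancy, and
  the population change in Atkinson equally-distributed-equivalent
  health, `EDE = (Σ w_q h_q^{1−ε})^{1/(1−ε)}`, is compared with the
  change in total health. Positive values mean the intervention narrows
  the health gap.

Around those sit a three-state (smoker / former smoker / dead) annual
Markov cohort model per quintile and arm; probabilistic sensitivity
analysis with the published parameter distributions; expected value of
perfect and partial perfect information (EVPI/EVPPI, GAM- and
GP-regression based); and ANCOVA variance decomposition of the PSA
outputs. Published parameter tables are shipped verbatim as fixtures;
inputs the source tables do not print (mortality, disease incidence,
baseline QALE, opportunity-cost shares, inequality aversion, the HRQoL
covariance, cost/disutility table) are generated by a documented
synthetic module, so absolute results illustrate the method rather than
reproduce the published figures. See the methods vignette
(`vignettes/dcea-uncertainty-methods.Rmd`) for the model, assumptions
and numerical choices.

## Worked example

```r
library(dceasmoke)

book <- fixture_parameter_book("england")   # published national table
ext  <- generate_external_inputs(seed = 1)  # synthetic external tables

# deterministic base case at the parameter means
base_case_results(book, ext)[["varenicline vs none"]]
#> <comparison_result: varenicline vs none>
#>   iNHB 54787.9 QALYs, iEDE 46917.1, inequality impact -7870.8 (win-lose)

# 1,000-draw probabilistic sensitivity analysis
psa <- run_psa(book, ext, n = 1000, seed = 42)
decision_probabilities(psa)[3, c("comparison", "p_inhb_pos", "p_delta_pos")]
#>                  comparison p_inhb_pos p_delta_pos
#> 3 varenicline vs ecigarette      0.773       0.127
```

Read: at the parameter means, offering varenicline rather than nothing
adds ~55,000 QALYs nationally but widens the deprivation health gap by
~7,900 EDE-QALYs ("win-lose" on the equity impact plane) — quit success
and service uptake rise with affluence while opportunity costs fall on
deprived quintiles. Against e-cigarettes, varenicline improves overall
health with probability 77% and reduces inequality with probability
13%; that residual decision uncertainty is what the VOI and ANCOVA
stages interrogate (they attribute it almost entirely to the two average
quit rates).

The `analysis/` directory holds the numbered drivers for the full
study — `01_parameters.R` … `06_local_authorities.R` — each of which
prints what it finds and writes its tables under `results/`.

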