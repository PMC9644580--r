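# cadcea

Cohort Markov cost-effectiveness analysis of **starting treatments for
stable coronary artery disease**: optimal medical therapy (OMT), stent
percutaneous coronary intervention (PCI) and coronary artery bypass
grafting (CABG).

The package is for health-economics analysts who want a tested, scriptable
pipeline for this class of decision problem: it generates synthetic
line-level patient records under a known ground truth, estimates
transition probabilities from records, evaluates a discounted,
half-cycle-corrected cohort Markov model, quantifies parameter uncertainty
with probabilistic sensitivity analysis (PSA), and compares
starting-treatment policies on incremental cost, QALYs and net monetary
benefit.

## The model

Patients move among nine states in 6-month cycles over a 10-year horizon
(20 cycles): `OMT`, the procedure states `PCI`, `CABG`, `RePCI` (with
one-time entry costs), the maintenance states `PostPCI`, `PostCABG`, the
long-term `StablePCI`, `StableCABG` states, and absorbing `Dead`.
Occupancy propagates deterministically, `n(c+1) = n(c) M(c)`, with the
row-stochastic matrix `M(c)` adjusted by a stepped background mortality
increment (+0.01 to the death probability every 10 cycles). Costs and
QALYs accrue per cycle with half-cycle correction (trapezoidal averaging
of adjacent occupancy vectors) and 3% annual discounting at cycle
mid-points:

```
total = sum_c  d(c) * [ sum_s  n_eff(s, c) * x(s) ]      d(c) = 1.03^-((c - 0.5) * 0.5)
```

Policies are mixes of starting arms — current practice is 81.9% OMT /
13.5% PCI / 4.6% CABG; the recommended policy is 86% OMT / 14% CABG — and
are scored per PSA draw as `NMB = lambda * dQALY - dCost` at a
willingness-to-pay of SGD 80,000 per QALY, with cost and utility
parameters drawn from gamma and beta laws matched to their mean/SD by
method of moments. Probabilities quoted over other horizons convert with
the cumulative-incidence relation `p_t = 1 - (1 - p_T)^(t/T)`.

## Worked example

```r
library(cadcea)

# a published 5-year event-free proportion as a 6-month probability
rescale_probability(64 / 70, 5, 0.5)
#> [1] 0.2178225

cfg <- analysis_config(
  output_dir = "cadcea_output",
  truth = default_ground_truth(n_patients = 10000, n_cycles = 20, seed = 1),
  n_draws = 1000, seed = 1
)
res <- run_pipeline(cfg)

res$comparison[, c("strategy", "delta_cost", "delta_qaly", "nmb")]
#>      strategy delta_cost delta_qaly   nmb
#> 1    all_cabg    16040.6    0.58986 31148
#> 2     all_omt    -3143.0   -0.05859 -1544
#> 3     all_pci    13601.7    0.15445 -1246
#> 4 recommended     -457.3    0.03219  3033

incremental_summary(res$psa, "recommended", "current_practice")
#> recommended vs current_practice (WTP 80,000/QALY)
#>   dCost       -457 (-2101 to 1028)
#>   dQALY      0.032 (-0.007 to 0.071)
#>   NMB         3033 (-426 to 6575)
#>   P(saves cost) 0.707  P(gains QALYs) 0.942  P(cost-effective) 0.957
```

Read: against current practice, the recommended policy saves SGD 457 per
patient and gains 0.032 QALYs on average under the shipped synthetic
ground truth, and is cost-effective at the threshold in 95.7% of draws.
Deltas are per patient over the 10-year horizon; `res$scaling` multiplies
them by an annual treated population (6,000 by default). Because the
original cohort's per-state transition probabilities are not published,
the shipped matrix is a documented synthetic stand-in (see the methods
vignette); magnitudes characterise the method, not any real population.

The bundle written to `output_dir` contains the records, the occupancy
trace, PSA draws, the policy comparison table, acceptability curves,
cost-effectiveness-plane samples, a cohort summary and a JSON manifest
(seeds + config hash) from which every number is reproducible. A thin CLI
over the same functions lives at `inst/cli/cadcea.R`
(`simulate | estimate | run | psa | report | all`).

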