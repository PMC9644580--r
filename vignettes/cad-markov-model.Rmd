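---
title: "A cohort Markov model for starting treatments in stable coronary artery disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cohort Markov model for starting treatments in stable coronary artery disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadcea)
```

## The decision problem

Patients presenting with stable coronary artery disease start on one of
three treatments: optimal medical therapy (OMT, at minimum antiplatelet
plus statin), stent percutaneous coronary intervention (PCI), or coronary
artery bypass grafting (CABG). The starting choice shapes long-run costs
and health because patients transition between treatments over time —
medically managed patients may later be revascularised, stented patients
may need repeat procedures. `cadcea` evaluates starting-treatment
*policies* (population mixes of starting arms) with a discrete-time cohort
Markov model and compares them on incremental cost, quality-adjusted life
years (QALYs) and net monetary benefit (NMB).

## Model structure

The state space is shipped as configuration data
(`default_model_structure()`), not code, so the topology can be edited
without touching the engine:

* `OMT` — medication-only management; may persist, move to either
  procedure, or die.
* `PCI`, `CABG`, `RePCI` — procedure states occupied for the cycle of the
  intervention; they carry a one-time entry cost.
* `PostPCI`, `PostCABG` — post-procedure maintenance on medication.
* `StablePCI`, `StableCABG` — long-term stable disease after a procedure,
  with a high probability of remaining stable.
* `Dead` — absorbing; zero cost and utility.

Each starting arm's journey diagram is the subgraph reachable from its
start state; `build_model()` rejects any transition probability placed on
an edge the structure does not allow.

The cycle length is 6 months and the horizon 20 cycles (10 years), chosen
to cover the treatment trajectory of stable disease. A cohort of 10,000
expected patients is propagated deterministically (`run_cohort()`);
parameter uncertainty is handled by the probabilistic sensitivity
analysis, not by microsimulation, so the cohort size only sets the scale
of the occupancy trace.

## Parameters

### Costs (SGD, gamma distributions)

Costs are modelled as gamma laws — right-skewed and nonnegative, matching
billing data in which most patients incur modest expenditures and a few
incur large ones. Each law is parameterised by its mean and standard
deviation and converted to shape/scale by the method of moments
(`gamma_from_mean_sd()`), so the quoted moments are reproduced exactly.

| parameter | mean (SD) | role |
|---|---|---|
| medication, no intervention | 129.86 (36.06) | per 6-month cycle in `OMT` |
| medication, after stent | 147.68 (14.29) | per cycle in `PCI`, `RePCI`, `PostPCI`, `StablePCI` |
| medication, after bypass | 96.65 (30.03) | per cycle in `CABG`, `PostCABG`, `StableCABG` |
| PCI procedure | 26,261.18 (4,908.53) | one-time on entry into `PCI`/`RePCI` |
| CABG procedure | 35,756.64 (4,419.17) | one-time on entry into `CABG` |

### Utilities (beta distributions)

Utilities lie in [0, 1] and are modelled as beta laws, again from
mean/SD by method of moments (`beta_from_mean_sd()`): OMT 0.69 (0.12),
PCI 0.72 (0.22), repeat PCI 0.70 (0.16), stable PCI 0.87 (0.03), CABG
0.82 (0.03), stable CABG 0.84 (0.04). Published shape pairs for some of
these utilities are mutually inconsistent with their quoted mean/SD (the
implied means differ by up to 0.15), so the mean/SD column is treated as
authoritative throughout and shapes are always re-derived. The
post-procedure maintenance states have no published utility of their own
and reuse the OMT utility, since patients there are again managed
medically.

### Transition probabilities

`estimate_transition_row()` estimates each row as the proportion of
patients observed in a state at one cycle who occupy each destination at
the next, pooled over patients and cycles (a time-homogeneous estimate; a
cycle-stratified variant is available via `by_cycle = TRUE`). The raw
tallies double as Dirichlet count evidence. Probabilities quoted over a
different horizon are converted with the cumulative-incidence relation

$$p_{t} = 1 - (1 - p_{T})^{t/T},$$

which assumes a constant event rate; `rescale_probability(64/70, 5, 0.5)`
turns a 5-year event-free proportion after bypass into the 6-month
probability 0.2178 of reaching the stable state.

### The default ground truth

The per-state transition probabilities of the original cohort are not
published, so the package ships a default matrix
(`default_transition_matrix()`) used both as the synthetic-data ground
truth and as the default model parameterisation. Two entries are anchored
on published 5-year event-free proportions (64/70 after bypass, 43/72
after angioplasty), rescaled to 6 months as above. The remaining entries
are the package's own clinically plausible choices, fixed once: the stent
pathway carries the higher long-run event burden implied by those same
proportions (a 0.035 per-cycle repeat-procedure hazard and per-cycle
death risks of 0.018–0.035), while the bypass pathway reaches its stable
state faster and the medication-only pathway is the cheapest. Under these
defaults the bypass-heavy policies gain QALYs and the medication-heavy
policies save costs — the qualitative structure the comparison is
designed to exhibit. Synthetic results quantify the *method*, not the
original cohort: absolute incremental values depend on this matrix and
should not be read as estimates for any real population.

## Engine numerics

* **Half-cycle correction.** Transitions can happen at any time within a
  6-month cycle, so each cycle's accruals use the mean of the occupancy
  vectors at its two ends (the life-table/trapezoidal method), and
  discounting uses the cycle mid-point. For constant flows this is
  equivalent to the conventional half-weighting of the first and last
  cycles.
* **Discounting.** 3% per annum, compounded: a flow at time $t$ years is
  multiplied by $1.03^{-t}$. With half-cycle correction off, flows are
  discounted at cycle ends.
* **Background mortality.** A stepped increment adds 0.01 to every live
  state's death probability per completed block of 10 cycles (cycles 1–10
  baseline, 11–20 +0.01), the most literal reading of an average death-rate
  increase of 0.01 every 10 cycles; non-death entries are rescaled to
  restore a unit row sum and the death probability is capped at 1. The
  increment is additive on the probability scale by default; a hazard-scale
  mode (`mortality_mode = "rate"`) is provided because the wording is
  ambiguous between the two. A user-supplied life table can replace the
  rule by editing the transition matrix per cycle.
* **Entry costs.** One-time procedure costs attach to the expected flow of
  *new* entrants into a procedure state each cycle (self-transitions are
  not entries) and are discounted at the cycle mid-point like other
  flows; patients placed in a procedure state at cycle 0 incur the entry
  cost at time 0 undiscounted.
* **Degenerate inputs.** A probability of 1 rescales to 1 for any shorter
  horizon; a single billing record has sample SD 0 by convention; ties at
  exactly zero delta count as *not* cost-saving and *not* cost-effective
  (strict inequalities throughout).

## Probabilistic sensitivity analysis

Each of 1,000 draws samples every cost and utility parameter once from
its gamma/beta law, evaluates all three starting arms deterministically
under that draw, and scores all five policies with the same draw (common
random numbers, so between-policy contrasts are not diluted by sampling
noise). By default only costs and utilities vary; transition rows can be
drawn from their Dirichlet count evidence with
`include_transitions = TRUE` when estimates carry counts. Uncertainty
intervals are equal-tailed 2.5–97.5 percentile intervals of the draws.
NMB is computed per draw as $\lambda \,\Delta Q - \Delta C$ at
willingness-to-pay $\lambda$ = SGD 80,000 per QALY (anchored to
per-capita GDP); the cost-effectiveness acceptability curve reports
$\Pr(\text{NMB} > 0)$ over a $\lambda$ grid.

## The five policies

Shipped as data in `default_strategies()`: current practice (81.9% OMT,
13.5% PCI, 4.6% CABG), the three 100% single-treatment policies, and the
recommended policy (86% OMT, 14% CABG, no stent PCI as a starting
treatment). A policy's result is the weights-weighted average of its arm
results, evaluated within each PSA draw.

## What the synthetic generator does and does not emulate

`generate_histories()` realises the ground-truth chain per patient at
cycle granularity, ending records at death (and optionally at a uniform
administrative censoring time, mirroring a fixed extraction window);
`generate_billing()` emits one gamma-distributed medication amount per
live patient-period, grouped by procedure history, plus one-time
procedure bills in a distinct group. This exercises every downstream
stage — estimation, censoring-by-death, cost summarisation — with a known
truth. It does **not** emulate visit-level timing, covariate-dependent
transition risks, correlated costs, or the joint demographic distribution
of a real registry (`generate_baseline()` is deliberately simple and
marginal). Passing tests therefore demonstrate correctness of the
machinery and recoverability of parameters at realistic sample sizes, not
fidelity to any particular hospital's case mix.

## Worked example

```{r example, eval = FALSE}
cfg <- analysis_config(
  output_dir = "cadcea_output",
  truth = default_ground_truth(n_patients = 10000, n_cycles = 20, seed = 1),
  n_draws = 1000, seed = 1
)
res <- run_pipeline(cfg)
res$comparison[, c("strategy", "delta_cost", "delta_qaly", "nmb")]
res$scaling
```

Problem sizes used by the shipped checks: the full pipeline example runs
10,000 synthetic patients and 1,000 PSA draws; parameter-recovery checks
use 50,000 patients; faster unit checks scale the cohort and draw counts
down (these sizes are the package's own verification choices).

## Known limitations

* Transitions are first-order Markov with no sojourn-time memory; no
  tunnel states beyond those the configuration encodes.
* The time-homogeneous estimator pools cycles; real transition risks may
  drift over a multi-year window.
* Billing-group assignment uses the most recent procedure, so a patient
  with both a stent and a bypass contributes to the most recent group
  only.
* No expected-value-of-perfect-information or tornado analysis is
  provided.
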