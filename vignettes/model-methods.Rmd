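---
title: "Model methods: a Markov cohort cost-utility model for SGLT2 inhibition in CKD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckdcea)
```

## The decision problem

Dapagliflozin slows the decline of glomerular filtration in chronic kidney
disease. Whether adding it to standard of care (ACEi/ARB background
therapy) is good value for a public payer depends on a trade-off played
out over decades: the drug is paid for now, while the savings — deferred
dialysis and transplantation, the two overwhelming cost drivers in CKD —
arrive years later. A lifetime Markov cohort model is the standard
instrument for this question, and that is what `ckdcea` implements,
together with the uncertainty analyses a reimbursement dossier requires.

## States and dynamics

The cohort occupies ten states: CKD stages 1–5 defined by eGFR bands
(stage 1 > 90 down to stage 5 < 15 ml/min per 1.73 m²), dialysis, a
transplant-surgery state, transplant maintenance, and death. The
transplant-surgery state is a *tunnel*: it is occupied for exactly one
cycle, attaches the one-off surgery cost, and empties into maintenance or
death. This split is the minimal construction that prices "initial" and
"maintenance" transplant costs separately, which the cost table does.

Dynamics are monthly and linear: \(x_{t+1} = x_t P\), with row-stochastic
\(P\) per arm and per phase. Phase 1 (cycles 1–4) is separated from
phase 2 (cycles 5+) because SGLT2 inhibition causes an acute, reversible
haemodynamic dip in eGFR in the first months that must not be read as
disease progression. Death is a column of the matrices — all-cause
mortality enters through the transition probabilities, not as a separate
hazard (one of the two readings the source description allows; we take
the one that keeps the model a single Markov chain).

Treatment discontinuation is a constant per-cycle probability. Within a
cycle the order is: discontinue first, then transition; the order is not
identifiable from outputs we have and is fixed for reproducibility.
Discontinued patients keep SoC dynamics and SoC costs forever (no
re-initiation), and the dead cannot discontinue. The whole comparator arm
lives in the "discontinued" stratum, which makes "discontinued ⇒
comparator dynamics and prices" a single code path. If the informing
transition matrices were estimated intention-to-treat they already embed
discontinuation, and an explicit rate double-counts it — the rate is
plain configuration and can be set to 0.

## Rewards

Rewards accrue to the state occupied at cycle start, cycles
\(t = 0, \dots, H-1\), with no half-cycle correction: at a 1-month cycle
the correction is bounded by half a cycle's reward (~0.04 life years
here) and is not worth the interpolation machinery. Costs and QALYs are
discounted at \((1.03)^{-t/12}\); life years are reported undiscounted,
matching the convention of the result tables this model format mirrors
(discounting life years is a reporting choice, not a modelling one, and
is switchable via `econ$annual_discount`).

Cost categories: drug acquisition (only in pre-dialysis states — practice
is to stop the drug at renal replacement therapy), per-stage disease
management, dialysis, transplant (one-off + maintenance), and adverse
events. Adverse events are *transient*: rather than tunnel states, they
enter as expected values — per-cycle rate × unit cost on alive occupancy,
and multiplicative utility decrements
\(u \cdot \prod_i (1 - r_i d_i)\), the ISPOR-recommended combination rule
for simultaneous decrements. With rates of order 10⁻³ per person-month
the expected-value treatment and an explicit event-state treatment agree
to far within parameter uncertainty.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| cycle length | 1 | month | resolution of the phase-1 eGFR dip |
| horizon | 480 | cycles | "lifetime": < 2 % of the fixture cohort is alive at 40 y; configurable |
| discount | 0.03 | per year | local HTA convention |
| WTP λ | 46,000 | RM/QALY | one GDP per capita |
| FX | 4.14 | RM/USD | reporting only, never internal |
| discontinuation | 0.004 | per cycle | **stand-in** (the rate is not published); ≈ 4.7 %/yr |
| treatment effect | 0.61 | — | hazard-ratio-like multiplier on monthly worsening probabilities |

Costs are 2022 RM and enter as annual amounts divided by 12; no inflation
machinery exists because the inputs are already inflated.

## The synthetic world

The packaged fixture transcribes the published cost and utility tables
exactly, but the trial-derived transition matrices and baseline
distribution are supplementary material not redistributable here, so the
generator (`synth_spec()` / `gen_parameter_set()`) builds a stand-in:

* each CKD state sends `worsen` mass to the next-worse state and `death`
  mass to death, and keeps the rest; dialysis additionally sends mass to
  transplant; maintenance can fail back to dialysis;
* the intervention arm multiplies every worsening probability by the
  effect factor (default 0.61, the trial's primary hazard ratio applied
  on the probability scale — legitimate at monthly probabilities of order
  10⁻²), the stay-probability absorbing the difference;
* worsening/death defaults were calibrated **once**, to the two published
  anchors for the comparator arm: life expectancy ≈ 9.5 years and ≈ 6
  years spent in CKD 1–3b (achieved: 9.64 and 6.02). Nothing else was
  calibrated;
* transition SEs are binomial at a pseudo sample size of 2,000
  (trial-sized precision); phase 1 equals phase 2; baseline mass sits on
  CKD 2–4 (11/31/33/25 %), the enrolled range;
* adverse-event rates per person-cycle are stand-ins of realistic order
  (10⁻³–10⁻⁵) with the trial's qualitative arm differences.

What a green test does **not** establish: agreement with the published
base case. The synthetic world reproduces the *structure* and the two
SoC anchors, not the trial's matrices; its lifetime effect is stronger
(ΔLY 0.81 vs the published 0.46) because a uniform 0.61 multiplier for
life is more favourable than trial-phase-specific matrices, and its total
costs are lower because the stand-in cohort spends less time on dialysis.
Dominance (cost saving with QALY gain), the direction of every cost
category, and all arithmetic identities are reproduced and tested.

## Sensitivity analyses

**One-way (tornado).** Each parameter in turn to mean ± SE (±10 %
probabilities/utilities, ±20 % costs when no SE), full deterministic
rerun at each end. The tornado is ranked by NMB width, not ICER width:
ICER is ill-behaved when ΔQALY crosses zero, NMB is linear. Ties sort by
parameter path, so output order is deterministic.

**Probabilistic.** Probabilities and utilities draw from beta, costs from
gamma, each matched by method of moments (`fit_beta`, `fit_gamma`, exact
closed-form inverses, tested to 1e-9). Matrix rows are sampled cell-wise
then renormalised — the literal reading of "beta for transition
probabilities"; a Dirichlet row model would be the natural alternative
and is a one-function change, but we keep the documented literal rule.
Cells at 0 or 1 and parameters with SE 0 pass through, so the zero-SE
limit returns the base case exactly. Each iteration owns a sub-seed drawn
once from the master seed, so results are bit-reproducible and adding a
parameter to the sampler cannot perturb other iterations.

On the fixture the probability of cost-effectiveness at λ = RM 46,000 is
≈ 0.86 (300 draws), noticeably below the 99.9 % a trial-based analysis
reports. This is a property of the stand-in uncertainty: per-cell
binomial SEs at pseudo-n 2,000 on *independently sampled* arm matrices,
plus a dialysis-utility SE of 0.17, make ΔQALY much noisier than the
(unpublished) trial SEs would. We report it as-is rather than shrink the
stand-in SEs toward the published figure.

## Numerical choices

* Row sums are validated to 1e-6 on load and renormalised exactly;
  the generator emits rows exact to the last ulp (tested at 1e-12).
* Occupancy conservation holds to 1e-10 over 480 cycles (tested).
* The microsimulation oracle shares `effective_matrix()` with the cohort
  engine, so it validates the *dynamics* (discontinuation order, phase
  switch, absorbing death) by categorical sampling, not a re-derivation.
  Agreement is asserted cell-wise at 3 binomial SEs with a multiplicity
  allowance (99.5 % of ~4,800 correlated cells inside 3 SE, all inside
  5 SE, discreteness floor 4/n) — the literal "max over all cells < 3 SE"
  is false with ~20 % probability for a *correct* engine.
* ICER is flagged undefined at ΔQALY = 0 rather than returned as ±Inf;
  NMB is always defined. Dominant draws count as cost-effective; NMB ties
  at exactly 0 do not.
* Currency is never rounded internally; USD columns round to whole units
  at the reporting layer only.

## Known limitations

* The fixture's matrices are synthetic; conclusions about the real drug
  should come from the trial's matrices loaded through the same config
  format.
* No heart-failure events or offsets, no indirect costs, no
  diabetes/heart-failure subgroups (all deliberately out of scope).
* CKD stage 1 is priced and permitted but unreachable in the generator
  (no improvement transitions); real matrices with improvement cells load
  and run fine.
* Expected-value adverse events understate variance relative to explicit
  event states (irrelevant for means, visible only in microsimulation
  tails).
* A constant discontinuation rate and a one-way switch are assumptions of
  convenience; both are config-exposed.
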