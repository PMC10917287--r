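# ckdcea

A Markov cohort cost-effectiveness model of dapagliflozin added to standard
of care (SoC) versus SoC alone in chronic kidney disease (CKD), from a
health-system (Malaysian public-payer) perspective.

## Who this is for

Health-economics and HTA analysts who need a transparent, fully tested,
script-driven implementation of the standard CKD state-transition
cost-utility model: eGFR-staged health states, renal replacement therapy,
monthly cycles, lifetime horizon, one-way and probabilistic sensitivity
analyses — with every input in plain-text configuration files and no
spreadsheet in the loop.

## The model

Ten ordered health states: CKD stages 1–5 (eGFR bands), dialysis, a
transient transplant-surgery state, transplant maintenance, and absorbing
death. A cohort \(x_t\) evolves by monthly row-stochastic matrices
\(x_{t+1} = x_t P\), with separate matrices for cycles 1–4 and 5+ (the
initial haemodynamic eGFR dip) and per arm. Patients on treatment
discontinue at a constant per-cycle probability and thereafter move (and
are costed) exactly like the comparator arm; treatment also stops at renal
replacement therapy. Transient adverse events (volume depletion, severe
hypoglycaemia, fracture, diabetic ketoacidosis, amputation) contribute
expected costs `rate × unit cost` and multiplicative utility decrements
`u · Π(1 − rate_i · d_i)` in the cycle of incidence.

Outcomes per arm: discounted (3 %/yr) costs by category and QALYs,
undiscounted life years. Comparison: incremental cost Δ*C*, QALYs Δ*E*,
ICER = Δ*C*/Δ*E*, and net monetary benefit NMB = λ·Δ*E* − Δ*C* at
λ = RM 46,000/QALY (one GDP per capita), with USD views at RM 4.14/USD.
Sensitivity analysis: NMB tornado over mean ± SE ranges (±10 %
probabilities/utilities, ±20 % costs when no SE), and a probabilistic
analysis drawing probabilities/utilities from method-of-moments beta and
costs from gamma distributions (1,000 Monte Carlo iterations by default).
A per-individual microsimulation oracle validates the cohort engine.

The packaged fixture (`fixture_path()`) transcribes the published cost and
utility tables exactly; its transition matrices and baseline distribution
are a **synthetic, clearly non-authoritative stand-in** calibrated so the
SoC arm lives ≈ 9.5 years with ≈ 6 of them in CKD 1–3b (the trial's
supplementary matrices are not redistributable here).

## Worked example

```r
library(ckdcea)
p <- load_parameters(fixture_path())
m <- run_model(p)
m$ce
#> <ckd_ce_result>
#>   d_cost RM -6259 | d_QALY 0.440 | d_LY 0.814
#>   ICER RM -14228/QALY | NMB RM 26493 | DOMINANT

psa <- run_psa(p, n_iter = 100, seed = 1, horizon = 240)
psa
#> <ckd_psa> 100 draws ( 0 failed ) seed 1
#>   mean d_cost RM -6333 | mean d_QALY 0.322 | P(CE at RM 46,000/QALY) = 0.860
```

Read: in the synthetic world the intervention is *dominant* — it saves
RM 6,259 per patient over a lifetime while adding 0.44 QALYs (0.81 life
years), because slower eGFR decline defers dialysis and transplantation.
A negative ICER under dominance is reported but not interpreted; the NMB
(RM 26,493 at λ = RM 46,000/QALY) is the stable summary. The probabilistic
analysis finds the intervention cost-effective in 86 % of draws under the
fixture's (deliberately wide) stand-in uncertainty.

Tornado and PSA from the command line:

```sh
Rscript inst/cli/ckdcea.R run --config inst/extdata/dapa_ckd_fixture --output-dir out
Rscript inst/cli/ckdcea.R dsa --config inst/extdata/dapa_ckd_fixture --output-dir out
Rscript inst/cli/ckdcea.R psa --config inst/extdata/dapa_ckd_fixture --output-dir out \
    --iterations 1000 --seed 1
Rscript inst/cli/ckdcea.R synth --output-dir my_world --effect 0.5
```

Outputs: `results.csv` (cost-category table with RM/USD columns),
`trace_<arm>.csv`, `tornado.csv`, `psa_draws.csv`, `ceac.csv`,
`psa_summary.csv`, `manifest.json`. Exit codes: 0 OK, 2 validation error,
3 runtime error.

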