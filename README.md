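# npccea

A three-state Markov cohort model comparing **gemcitabine + cisplatin
(GP)** against **docetaxel + cisplatin + fluorouracil (TPF)** induction
chemotherapy for locoregionally advanced nasopharyngeal carcinoma, from
the Chinese healthcare-system perspective.  It is written for health
economists and methodologists who want a fully scripted, testable
version of this class of oncology cost-utility analysis: every input is
an explicit parameter, every published quantity is either reproduced by
computation or flagged as an assumption, and the whole pipeline — from
survival-curve digitization artifacts to the cost-effectiveness
acceptability curve — runs from code alone.

## The model

Patients occupy one of three states — disease-free survival (DFS),
progressed disease (PD), death — over 173 cycles of 21 days (10 years),
starting in DFS.  Survival is parametric,

    S(t) = exp(-λ t^γ)        (exponential: γ = 1; t in 21-day cycles)

with per-cycle transition probabilities
`tp(k) = 1 − S(ku)/S((k−1)u)`.  In the default decomposition the
OS-curve death probability applies to every alive state (so cohort
deaths reproduce the OS curve exactly) and the DFS-curve probability
routes DFS to PD.  Cycle-indexed costs cover induction drugs (priced by
whole single-use vials, with an exact-dose alternative for the wastage
scenario), adverse-event management, chemoradiotherapy, time-banded
follow-up, and subsequent therapy versus best supportive care in PD.
Discounted totals (3%/year) give costs, life-years and QALYs (utilities
0.76 DFS / 0.57 PD), compared as

    ICER = ΔCost / ΔQALY,     NMB(w) = w·QALY − Cost,

with dominance classified instead of dividing when a quadrant has no
trade-off.  One-way sensitivity analysis re-evaluates the full model at
each parameter bound; probabilistic sensitivity analysis draws gamma
(costs), beta (probabilities, utilities) and log-normal (survival scale)
parameters over 10,000 Monte Carlo replicates.

## Worked example

```r
library(npccea)

spec <- npc_model_spec()          # the complete two-arm specification
ev   <- evaluate_model(spec)      # base case, vial-based drug pricing
results_table(ev)
#>   scope arm    cost      ly    qaly inc_cost inc_qaly icer_per_qaly
#> 1 total  GP 39371.2 8.03269 5.60150  3979.54 0.430595       9241.96
#> 2 total TPF 35391.7 7.34772 5.17091       NA       NA            NA
#> 3   dfs  GP 20058.0 5.38352 4.09147 -1176.79 0.160650      -7325.18
#> 4   dfs TPF 21234.8 5.17214 3.93082       NA       NA            NA
#> 5    pd  GP 19313.2 2.64917 1.51003  5156.33 0.269946      19101.37
#> 6    pd TPF 14156.8 2.17559 1.24008       NA       NA            NA

ev$comparison
#> <ce_comparison> dCost $3979.54, dEffect 0.4306 QALY -> icer ($9241.96 per QALY)
```

GP buys 0.43 extra QALYs for an extra $3,980 — an ICER of about $9,242
per QALY, far below the $31,008.16 willingness-to-pay threshold (3x
China's 2019 per-capita GDP).  In the DFS state GP is both cheaper and
more effective (it dominates); the extra spending is concentrated in the
PD state, where more GP patients receive subsequent therapy.

Uncertainty:

```r
ps <- run_psa(spec, n_samples = 10000, seed = 1)
ceac(ps, c(10336.05, 20672.11, 31008.16))
#>        wtp probability
#> 1 10336.05      0.5490
#> 2 20672.11      0.7482
#> 3 31008.16      0.8295
```

At the 3x-GDP threshold GP is cost-effective in about 83% of
replicates.  `owsa(spec)` ranks parameters in a tornado table (the cost
and proportion of subsequent treatment dominate), and
`evaluate_model(spec, wastage = "exact_dose")` re-prices chemotherapy by
administered milligrams instead of whole vials.  `run_base_case()`,
`run_owsa_report()` and `run_psa_report()` write the CSV tables, JSON
summaries and figures for each analysis.

The time unit of the survival parameters (21-day cycles) is an explicit
modelling decision; check it against published landmarks with:

```r
implied_survival_summary(arm_survival(spec, "GP", "dfs"), c(3, 10))
#>   years  survival
#> 1     3 0.8086972   # published 3-year DFS: 83.1%
#> 2    10 0.2796703
```

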