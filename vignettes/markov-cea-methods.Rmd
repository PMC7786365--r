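---
title: "Methods: a three-state Markov cohort model for induction chemotherapy in nasopharyngeal carcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-state Markov cohort model for induction chemotherapy in nasopharyngeal carcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npccea)
```

## The decision problem

`npccea` implements a cost-utility comparison of two induction chemotherapy
regimens for locoregionally advanced nasopharyngeal carcinoma, from the
perspective of the Chinese healthcare system: gemcitabine plus cisplatin
(GP) versus docetaxel, cisplatin and fluorouracil (TPF), each given for
three 3-week cycles and followed by cisplatin-based concurrent
chemoradiotherapy (CCRT).  Outcomes are discounted lifetime costs (2020
USD), life-years (LY), quality-adjusted life-years (QALY) and the
incremental cost-effectiveness ratio (ICER), judged against a
willingness-to-pay (WTP) of three times China's 2019 per-capita GDP
($31,008.16 per QALY).

## Model structure

The cohort moves through three mutually exclusive states — disease-free
survival (DFS), progressed disease (PD) and Death — in discrete cycles of
21 days, matching the treatment schedule.  Everyone starts in DFS.  The
horizon is 10 years, i.e. `floor(10 * 365.25 / 21) = 173` complete cycles;
partial cycles beyond the last complete one are discarded.  Costs and
effects are discounted at 3% per year with the per-cycle factor
`(1.03)^(-21/365.25)`; rewards accrue on end-of-cycle occupancy (a
half-cycle correction is available via `model_config()` but off by
default, consistent with decision-software defaults when no correction is
reported).

### Survival laws and their time unit

Each arm carries a DFS and an OS law of the form
`S(t) = exp(-lambda * t^gamma)` (`gamma = 1` for the exponential).  The
published scale/shape estimates come without a time unit.  We resolved
this empirically with `implied_survival_summary()`: only when `t` counts
21-day cycles do all four fitted laws land on the published 3-year
Kaplan-Meier landmarks (DFS 83.1/81.6%, OS 94.4/92.0%) to within about
1.5 percentage points; per-month or per-week readings miss by 5-15
points.  The unit is therefore `"cycles"` and remains an explicit,
checkable field of every `parametric_survival()` object.

### Transition probabilities

The per-cycle exit probability of a curve is
`tp(k) = 1 - S(k u)/S((k-1) u)`.  Two decompositions into the three-state
schedule are implemented in `build_transition_schedule()`:

* **independent** (default): DFS loses `tp_dfs(k)` to PD, and *every*
  alive state loses `tp_os(k)` to Death.  The alive fraction then equals
  `S_os(k u)` exactly, so cumulative deaths reproduce the OS curve by
  construction.  This is the conventional partitioned structure for
  models built directly from published DFS and OS curves, and it is the
  only decomposition that reproduces the published per-state results:
  the two fitted DFS Weibull curves cross at about four years, and
  only this scheme keeps the GP arm ahead of TPF in DFS time the way the
  source analysis reports.
* **hazard_partition**: the DFS exit probability is split between PD and
  Death, with the direct DFS-to-Death flow capped by `tp_os(k)` and the
  PD-to-Death probability calibrated each cycle so cumulative deaths
  track `1 - S_os(k u)`.  Under this scheme DFS occupancy equals
  `S_dfs(k u)` exactly, and identical DFS/OS curves send no one to PD.

Probabilities that would leave `[0, 1]` are clamped; clamped cycles are
recorded in the schedule's `clamped_cycles` attribute and a warning is
raised only if the death-tracking deficit persists to the horizon end.
For the GP arm the fitted OS hazard exceeds the DFS hazard during
roughly the first month (a side effect of fitting the two curves
independently), so under the partition scheme a small transient deficit
arises before any PD mass exists; it is fully reabsorbed within a few
cycles.

## Costs

All costs are cycle-indexed, in 2020 USD (1 USD = 6.8606 RMB, recorded as
metadata only):

* **Induction (cycles 1-3)**: drug acquisition (gemcitabine + cisplatin,
  or docetaxel + fluorouracil + cisplatin + prophylactic G-CSF),
  hydration, antiemetics, hospitalization and laboratory tests, per arm.
* **Cycle 1 one-times**: PICC line placement (rate parameter, default 1,
  exposed because only its cost is published) and the expected
  adverse-event management cost, `sum(p_i * c_i)` over AE classes.
  The published record gives grade 3-4 leucopenia (14.08% GP / 34.48%
  TPF) and neutropenia (14.08% / 24.14%) rates with per-episode
  management costs per grade band; the probability of a costed grade 1-2
  episode is not published and is set to a neutral 0.50 in both arms
  (±20% range).  Its leverage is tiny: the grade 1-2 unit costs differ
  between arms by only $27, so the assumption moves the incremental cost
  by about $13.
* **CCRT (cycles 4-6)**: radiotherapy per cycle plus concurrent cisplatin
  (100 mg/m² on day 1 of each CCRT cycle, priced from the vial
  catalogue since it has no published cost row), with radiotherapy
  preparation and pre-treatment imaging charged once at cycle 4.
  Hydration/antiemetic/hospitalization rows are attached to the
  induction cycles where their published values sit.
* **Follow-up (cycle 7 onward, DFS only)**: $147.26 per cycle in years
  0-2 (the published quarterly cost of $631.10 times 21/90 — the
  package's `period_to_cycle_cost()`), then the published per-cycle
  values $81.58 (years 3-5) and $40.79 (years 6-10) verbatim, because
  their implied period lengths are not clean multiples of the cycle.
  Bands are assigned by end-of-cycle time.
* **Progressed disease (every PD cycle)**: a mix of subsequent therapy
  (75.0% of GP patients at $541.36/cycle; 68.2% of TPF at $524.08) and
  best supportive care ($52.53) for the remainder.

### Drug wastage

Chemotherapy doses are body-surface-area based (representative BSA
1.72 m², configurable) while drugs come in single-use vials, so the base
case prices every administration as the cheapest covering combination of
whole vials.  The alternative `exact_dose` policy prices administered
milligrams only; it can never cost more, per administration, than the
vial-based policy.  The vial catalogue is **synthetic**: realistic
Chinese vial sizes (gemcitabine 1000/200 mg, cisplatin 20/10 mg,
docetaxel 20 mg, fluorouracil 250 mg) whose per-milligram prices are
calibrated once so that vial-based pricing reproduces the published
per-cycle acquisition costs exactly; the study's own vial-level data are
unpublished, so the absolute size of the wastage saving is an estimate,
while its sign and the scenario's ICER are testable.

## Economic outputs

`run_arm()` accrues discounted cost, LY and QALY per arm, decomposed by
state (utilities 0.76 for DFS, 0.57 for PD, 0 for Death).
`compare_arms()` computes incremental cost and effect and classifies the
result: an ICER in the trade-off quadrants, dominance otherwise, with
exact ties resolved toward the cheaper or more effective arm and flagged
`weak` so no undefined ratio is ever formed.  `net_monetary_benefit()`
(`wtp * QALY - cost`) linearises the decision rule; its incremental sign
agrees with `ICER < WTP` in the trade-off quadrant by construction.

## Sensitivity analysis

**One-way (tornado)**: every parameter with a published or rule-based
range is set to each bound in turn and the *full* model re-evaluated —
no linear approximation.  Ranges without published bounds use the ±20%
rule (`default_range()`).  The discount rate is varied in one-way
analysis only.

**Probabilistic**: 10,000 Monte Carlo replicates redraw every uncertain
parameter, rebuild both arms and record `(dCost, dQALY)`.  Distribution
assignment follows standard health-economics practice: gamma for costs
and beta for probabilities and utilities, parameterised by
method-of-moments from the published mean and range read as a 95%
interval (`se = (high - low)/3.92`); an infeasible beta variance is
truncated to 95% of the feasible maximum.  Survival-curve uncertainty is
propagated as a log-normal draw of each **scale** parameter at its
published standard error, holding the Weibull shape at its estimate.
This choice deserves its own paragraph.

Scale and shape estimates of a Weibull fit are strongly negatively
correlated — refitting simulated cohorts of this study's size under
administrative censoring puts the log-scale correlation near −0.98.
Drawing the two independently therefore grossly overstates uncertainty
in the extrapolated tail and, because survival enters the outcomes
convexly, shifts the *mean* incremental QALY of the PSA far away from
the base case.  Drawing them jointly at a correlation that strong does
the opposite: the cumulative-hazard variance nearly cancels across the
observed range and the PSA becomes implausibly confident.  The exact
covariance of the source fits is unpublished, so the package's default
propagates the level uncertainty of each curve (the scale draw at its
published SE) with the hazard's shape anchored at the fitted trend.
Joint correlated draws remain available: mark the shape parameter
`lognormal` and set `scale_shape_corr` in the arm's survival entry.
The published per-curve correlation coefficients are interpreted as the
`log(-log S)` regression diagnostic, not the parameter correlation,
because one is also printed for the single-parameter exponential fit.

`ceac()` turns the samples into a cost-effectiveness acceptability
curve: the fraction of replicates with `wtp * dQALY - dCost > 0` at each
threshold.  The PSA is bit-reproducible given its seed.

## Synthetic data

No patient-level data are distributed.  `simulate_ipd()` draws censored
time-to-event records from any model law by inverse transform
(`t = (-log U / lambda)^(1/gamma)`); `km_estimate()` turns them into the
product-limit curve with numbers at risk, i.e. exactly the container a
curve digitizer would produce; `reconstruct_pseudo_ipd()` inverts that
(events per interval `d = (n + n')(1 - R)/(1 + R)` with `R` the interval
survival ratio, censoring spread evenly, largest-remainder rounding so
event plus censoring counts match the at-risk decrement exactly, and
survivors censored at the last boundary); `fit_parametric()` refits by
maximum likelihood with observed-information standard errors and reports
the adjusted R² and correlation of the `log(-log S)` versus `log t`
regression as the goodness-of-fit diagnostic.

What the generator emulates: parametric event processes, administrative
or uniform censoring, digitization at interval boundaries, and the
two-arm parameter fixture (`npc_model_spec()`) with every published
mean, range, probability and threshold.  What it does not emulate:
digitization noise in the curve ordinates, patient-level cost
heterogeneity, covariates, or real-world deviations from the parametric
families.  Passing round-trip and recovery tests therefore shows the
pipeline is internally consistent, not that the parametric extrapolation
of any particular real dataset is correct.  The published adjusted-R²
values are for that reason a diagnostic, not a reproduction target: they
depend on the unpublished at-risk tables of the source figures.

## Numerical choices and problem sizes

* Trace conservation and row-stochasticity are enforced to 1e-12;
  the engine matches the geometric-series closed form to 1e-10 in the
  all-exponential case.
* Pseudo-IPD event/censoring allocation uses largest-remainder rounding
  within each interval, preserving interval totals exactly.
* The exponential standard error, if ever needed from data alone, is the
  event-count rule (`1/sqrt(d)` on the log-hazard scale); published SEs
  are used directly when supplied.
* Default analysis sizes: 173 cycles per arm evaluation, 10,000 PSA
  replicates, parameter-recovery tests at n = 150 with ~30% censoring
  and consistency tests at n = 10,000.  A full PSA takes well under a
  minute on one core.

## Known limitations

* The DFS/OS reconciliation is structurally under-specified by any pair
  of marginal curves; both supported decompositions are exact for
  different margins, and the default was selected because it reproduces
  the published per-state decomposition.  A post-progression survival
  model would remove the ambiguity but none is published.
* Grade 1-2 adverse-event probabilities, the PICC insertion rate, the
  CCRT-phase cisplatin cost and the vial catalogue are assumptions
  (documented above) because the underlying records are unpublished;
  each is an explicit, perturbable parameter.
* Utilities are literature-derived constants; no time-varying or
  treatment-specific quality of life.
* Two arms only; no efficiency frontier, correlated-parameter sampling
  or value-of-information analysis.
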