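---
title: "A Markov cost-effectiveness model of combination therapy for BPH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cost-effectiveness model of combination therapy for BPH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

Lower urinary tract symptoms from benign prostatic hyperplasia (BPH) are
common in men over 50.  Alpha-blockers such as tamsulosin relieve
symptoms without altering disease progression; adding a
5-alpha-reductase inhibitor (dutasteride) reduces the risk of acute
urinary retention (AUR) and of progression to surgery (transurethral
resection of the prostate, TURP), at a substantially higher drug price.
This package implements the decision-analytic model used to ask, from a
public-payer perspective with 2018 US-dollar costs: is daily
dutasteride/tamsulosin combination therapy worth its extra cost compared
with tamsulosin alone, in incremental cost per quality-adjusted life
year (QALY) gained?

```{r}
library(bphce)
params <- base_case_parameters()
params
```

## Model structure

The model is a Markov state-transition chain over seven health states:

* **BPH** — symptomatic disease on medication; the whole cohort starts
  here.  Severity strata are deliberately collapsed into one state with
  a severity-weighted utility (0.876).
* **AUR** — an acute retention episode; a one-cycle tunnel state.  A
  fraction `p_aur_to_turp` (0.8) proceeds to surgery, the remainder
  returns to BPH.
* **TURP** and **REPEAT_TURP** — surgical cycles, also tunnels.  TURP
  carries a 30-day surgical mortality (0.0237) charged in the surgical
  cycle; survivors recover, need long-term medication, or (from the
  first TURP) need repeat surgery.  A patient receives at most two TURP
  procedures, ever.
* **MEDICAL_INTERVENTION** — long-term pharmacological management after
  surgery; patients here may still progress to a second TURP.
* **RECOVERY** — post-surgical recovery at full utility; patients may
  later need medical intervention.
* **DEATH** — absorbing; pools surgical and background all-cause
  mortality.

Cycles are one year; the cohort ages through a life table as cycles
advance.  Both cost and QALYs are discounted at 3% per year with
cycle-start accrual (no half-cycle correction by default; a flag
enables it).

The at-most-two-TURPs rule is *structural*: internally the chain runs
on nine states, with `MEDICAL_INTERVENTION` and `RECOVERY` split by the
number of TURPs already received, and the post-second-TURP copies have
no surgical exit.  No simulated path can therefore ever contain a third
procedure — a property the test suite audits on microsimulated paths.

Treatment enters in exactly one place: in the combination arm the BPH
exits toward TURP and AUR are scaled by `1 - rrr` with the published
4-year relative risk reductions (0.706 and 0.676).  The same per-cycle
reduction is applied at every horizon; no efficacy waning is modelled.

## Reading the published transition rows: why rows are renormalized

The published per-cycle transition block is internally inconsistent in
two ways, and the package had to take a documented position on each.

**Stay weights.**  The printed "remain" probabilities do not complete
their rows: for BPH, 0.345 (stay) + 0.021 (TURP) + 0.004 (AUR) = 0.37,
not 1.  Two readings are implemented:

* `row_mode = "renormalize"` (default): the printed stay weight and
  exit probabilities are treated as relative weights and rescaled to
  sum to one, giving e.g. an effective annual BPH→TURP probability of
  0.021/0.37 ≈ 0.057.
* `row_mode = "residual"`: the printed exit probabilities are used
  literally and the self-loop absorbs the remainder (stay ≈ 0.975).

The renormalized reading is the default because it is the one that
reproduces the published results: with it the 4-year incremental cost,
incremental QALYs and ICER land within a few percent of the published
values, whereas the residual reading yields roughly four-fold fewer
surgical events and an ICER near 41,000 USD/QALY against a published
11,651.  The residual reading remains available for exploration.

**Timescale.**  The block is headed "monthly" but the published
analysis adopts one-year cycles, and the published ~3.4 of 4
person-years spent in BPH is only consistent with the annual reading.
The probabilities are therefore applied per annual cycle by default;
`probability_timescale = "monthly"` converts them via
`p_a = 1 - (1 - p_m)^12` for users exploring the alternative reading
(in that mode rows use residual stays, since the printed stay weights
are not convertible as event probabilities).

Two further conventions, both recorded in
`inst/extdata/parameter_map.csv` (one row per published input, the
field it maps to, and whether it is used): the redundant "TURP patients
who recover = 1 / fully recover = 0.998" rows are resolved by treating
recovery as the survivor remainder (0.998 is stored but unused), and
"patients on medication who transition to AUR = 0" is taken to
foreclose all post-surgical AUR, which the chain enforces structurally.

## Cost and utility accrual

Costs decompose into five categories, mirroring the published layout:

* **drug** — the arm's annual acquisition cost, accrued in *all alive
  states*.  The published lifetime monotherapy drug cost equals the
  annual tamsulosin price times discounted alive person-years to the
  dollar (856 = 55.79 × 15.34), which identifies this accrual rule;
  restricting accrual to the BPH state (`drug_accrual = "bph"`) is
  available behind a flag and yields roughly half that figure at the
  lifetime horizon.
* **bph** — annual disease-management cost on BPH occupancy.
* **aur** — the per-episode retention cost, charged per AUR tunnel
  cycle.
* **turp** — the per-procedure cost, charged per TURP or repeat-TURP
  cycle; deaths in the surgical cycle still incur it.
* **medical** — the annual medication cost on medical-intervention
  occupancy, plus an optional one-off follow-up cost on entering
  recovery from a surgical state (`recovery_followup`, 0 by default
  since no such price is published).

QALYs apply each state's utility weight to its occupancy per cycle.
Episode counts are undiscounted: BPH person-years, AUR episodes, TURP
procedures (tunnel occupancies equal event counts), and cumulative
deaths.

```{r}
rc <- run_cohort(params, "combination", 4, trace = FALSE)
rm_ <- run_cohort(params, "monotherapy", 4, trace = FALSE)
compute_icer(rc, rm_)
```

## Background mortality stand-in

The published model drew all-cause mortality from the territory's life
table, which is not reproduced in print.  The package ships a Gompertz
stand-in, hazard `b * exp(0.085 * age)`, with `b` solved in closed form
so the 4-year cumulative background mortality of the starting cohort
(age 66 by default — the trial enrolled men over 50 and the published
4-year death fractions imply a cohort in its mid-to-late sixties) is
0.0538.  That target was chosen once so total 4-year deaths in the
monotherapy arm, background plus surgical, match the published 0.0577;
the implied annual probabilities (≈0.012 at 66) are realistic for male
all-cause mortality at these ages.  The stand-in is synthetic: it
reproduces the level and age-slope of late-adult mortality but not
cohort effects or the old-age deceleration of a real life table.

## Engines

`run_cohort()` propagates occupancy deterministically; it is the
reference engine and the inner engine of both sensitivity analyses.
`run_microsimulation()` samples individual patient paths through the
same matrices under an explicit seed, returning the per-patient event
log; it exists to track event counts and to demonstrate convergence —
the test suite verifies agreement with the cohort engine within
Monte-Carlo error and the `1/sqrt(n)` error rate.  The cohort engine is
itself verified to `1e-9` against closed-form geometric-series oracles
on degenerate toy chains (`make_toy_model()`,
`closed_form_occupancy()`), computed before the engine is trusted and
never from the engine itself.

## Sensitivity analyses

`run_owsa()` varies one parameter at a time over its published range
(deterministic cohort ICER at each bound, table sorted by spread).
Note a structural consequence of row renormalization: ranges printed
for raw probabilities act on renormalized weights, so the BPH surgery
risk and stay weight produce the largest spreads and the extreme ICERs
(≈4,900–23,200 USD/QALY over the 4-year horizon) exceed the published
6,000–17,000 band, which listed drug price as the top bar.  The ranges
are applied exactly as printed; the discrepancy is a consequence of the
row-reading required to reproduce the base case, and is reported, not
calibrated away.

`run_psa()` performs second-order Monte Carlo: each draw samples the
published beta/gamma distribution set jointly
(`sample_psa_parameters()`), runs both arms through the cohort engine
on the same drawn parameters, and records one incremental (cost, QALY)
pair — pure parameter uncertainty, with a nested microsimulation mode
behind a flag.  Gamma rates are rederived as `shape / printed mean`
because the printed rates contradict the printed means by orders of
magnitude; the printed shapes (hence dispersion ordering) are kept.
Only the eleven published distributions are sampled; utilities, drug
prices and the remaining transitions stay fixed (they carry only
one-way ranges).  The AUR→TURP fraction has a range but no
distribution: the one-way analysis varies it, the probabilistic one
does not.  `compute_ceac()` counts draws with strictly positive
incremental net monetary benefit (a tie counts as not cost-effective).

A caveat the package makes no attempt to hide: several distribution
means differ from the deterministic base-case values by up to
five-fold (e.g. the BPH→AUR probability, 0.02 versus 0.004), and the
AUR-cost gamma (shape 0.21) is extremely right-skewed.  Both tables are
preserved verbatim in their respective roles — the base case follows
the deterministic input table, the PSA follows the distribution table —
so the PSA scatter centres away from the deterministic base case and
its spread is wide: the computed acceptability at one GDP per capita
(45,887 USD/QALY, 4-year horizon) is about two thirds, against a
published 97%.

## Numerical choices

* Tolerances: matrix rows must sum to 1 within `1e-12`; cohort
  occupancy is checked against the simplex at `1e-9` each cycle;
  engine-versus-oracle tests run at `1e-9`.
* Ties: zero incremental cost or QALYs are classified to the positive
  quadrant side and flagged; zero incremental NMB counts as not
  cost-effective; an exactly zero QALY difference yields an undefined
  ICER signal, never a crash.
* Degenerate inputs: a zero discount rate, zero hazards (`b = 0` life
  table), empty configuration documents, and single-patient
  microsimulations are all legal and tested.
* Invalid PSA draws (possible only in residual row mode, where sampled
  exits can sum past one) are resampled and counted.
* Seeds: every stochastic entry point (`run_microsimulation`,
  `sample_psa_parameters`, `run_psa`) requires an explicit integer seed
  and is bit-reproducible under it.

## Problem sizes

The shipped analyses use the published sizes: 10,000 microsimulated
patients for the base case and 10,000 Monte Carlo draws per horizon for
the PSA.  The test suite uses smaller draw counts for properties that
do not need the full size, and up to 200,000 patients where convergence
rates are measured on toy chains.

## What the synthetic fixtures do and do not show

The toy chains and random parameter sets exercise the arithmetic of the
engines — discounting, accrual, competing risks, renormalization — under
known answers, and the life-table stand-in reproduces the aggregate
mortality the published model implies.  None of this validates the
clinical content: the transition probabilities come from a single
hospital cohort, efficacy from one trial, and utilities from published
mappings, so passing tests certify a faithful re-implementation of the
published model, not the model's external validity.

## Known limitations

* The published episode counts (AUR 0.08/0.11, TURP 0.22/0.29 over 4
  years) imply a weaker realized treatment effect (~27–32% reductions)
  than the published relative risk reductions (67.6%/70.6%) produce
  under any reading this package implements; the printed incremental
  cost, QALYs and ICER are reproduced, the printed episode counts are
  not.  Both cannot hold at once.
* At the lifetime horizon the published TURP count (2.62 per
  monotherapy patient) exceeds the structural two-procedure cap the
  published assumptions themselves state; with the cap enforced, the
  model yields fewer lifetime events, smaller TURP savings, and a
  larger lifetime QALY gain than published (the per-cycle risk
  reduction compounds for 35 years; the published lifetime deltas are
  consistent with an effect confined to the 4-year trial window, a
  waning the model deliberately does not implement).
* No adverse events, no severity strata, no societal costs, no
  currency conversion — all deliberately out of scope.
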