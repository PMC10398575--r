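---
title: "Methods: a partitioned-survival cost-effectiveness model for first-line immunochemotherapy in mNSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned-survival cost-effectiveness modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem

Adding a limited course of tremelimumab (CTLA-4 blockade) and durvalumab
(PD-L1 blockade) to first-line platinum chemotherapy improves
progression-free and overall survival in metastatic non-small cell lung
cancer, at a drug cost an order of magnitude above the chemotherapy
backbone. The package models the lifetime trade-off from a U.S. payer
perspective: discounted direct medical costs against quality-adjusted
life-years (QALYs), summarized as an incremental cost-effectiveness ratio
(ICER) judged against a $100,000–150,000/QALY willingness-to-pay range.

## Model structure and conventions

Three mutually exclusive states — progression-free (PFS), progressed
disease (PD), dead — on a 1-month cycle over a 200-month horizon (long
enough that under every parameterization we use, more than 98% of the
cohort has died; survivors past that point contribute negligibly). This is
a *partitioned-survival* model: state occupancy is read directly off the
endpoint survival curves rather than derived from transition intensities,

* p_PFS(t) = S_PFS(t),
* p_death(t) = 1 − S_OS(t),
* p_PD(t) = S_OS(t) − S_PFS(t).

Conventions, chosen to match the analysis this package re-implements:
costs and QALYs accrue at the **beginning of each cycle** with **no
half-cycle correction**; discounting is 3% per year applied as
(1.03)^(−t/12) at monthly resolution; all prices are 2022 USD (any
inflation adjustment happens upstream of the model).

Two structural safeguards handle extrapolation artifacts:

* **Background mortality floor.** Extrapolated OS hazards are floored at
  period life-table hazards for the ageing cohort (start age 64 by default,
  a typical mNSCLC trial median — an assumption, configurable):
  h_eff = max(h_disease, h_background), with h_background =
  −log(1 − q(⌊age⌋))/12. The floor can only lower survival, never raise it.
  The packaged life table is a synthetic Gompertz–Makeham schedule that
  tracks a recent U.S. period table in shape and magnitude; users supply a
  real table as `age,qx` text via `read_life_table()`.
* **Curve crossing.** Independently extrapolated PFS can exceed OS in the
  tail; PFS is then capped at adjusted OS and the PD share clamped at zero,
  with a warning. Arms and endpoints are fitted independently (no
  proportional-hazards coupling), mirroring the source analysis.

## From published figures to patient-level data

The evidence base is digitized Kaplan–Meier coordinates plus printed
numbers-at-risk rows. `reconstruct_ipd()` recovers pseudo individual
patient data by interval-wise integer allocation: within each
inter-risk-time interval, censoring times are spread uniformly, event
counts at each digitized drop are set from the published survival ratios
given the running at-risk count, and the interval's censoring total is
adjusted by a deterministic fixed-point iteration (with an exhaustive
fallback scan) until the implied number at risk matches the printed value
exactly. Survivors at the last at-risk time are censored there. Ties and
rounding are resolved deterministically, so reconstruction is
reproducible bit for bit. On synthetic trials of 300–340 patients per arm
the KM curve of the reconstruction matches the digitized curve to within
about 0.001–0.002 absolute, far inside the 0.02 tolerance we require in
tests.

## Parametric extrapolation

Seven families are fitted by right-censored maximum likelihood
(delegated to `flexsurv`, with up to three jittered restarts): exponential,
Weibull, log-normal, log-logistic, gamma, generalized gamma (Prentice
location/scale/shape form, for numerical stability), Gompertz. Selection
is by AIC; when BIC disagrees the AIC choice is kept and the disagreement
logged. Gompertz fits with negative shape are rejected outright: they are
defective (S(∞) > 0) and unusable for lifetime extrapolation. The
log-logistic is parameterized as S(t) = 1/(1 + (t/scale)^shape), making the
median equal to the scale in months and the heavy tail explicit —
the family the source analysis selected for all four curves.

Medians are analytic where the family permits (log-logistic, exponential,
Weibull) and otherwise bracketed root-finding to 1e-6 months over ten
horizons.

## Inputs and their provenance

Every uncertain input is a `ce_param` carrying `value, low, high,
distribution, provenance`. Provenance is one of:

* `paper` — publication-reported: utilities 0.673 (PFS), 0.473 (PD), 0
  (dead); 3%/yr discounting; 200-month horizon; body surface area 1.86 m²;
  second-line uptake 40.8% (T+D+CT) / 60.2% (CT); the dose calendars
  (tremelimumab 75 mg at 21-day treatment cycles 1–4 and 6; durvalumab
  1,500 mg cycles 1–6 then every 4 weeks until progression; cisplatin
  75 mg/m² + pemetrexed 500 mg/m² for four cycles with pemetrexed
  maintenance for non-squamous disease).
* `derived` — arithmetic consequences of published ranges: per-cycle prices
  of durvalumab ($11,693.25) and tremelimumab ($10,981.60) are the upper
  ends of the published downward-only price slides, which are exactly 125%
  of the lower ends — identifying the upper end as the base value under the
  stated 20% variation.
* `calibrated` — log-logistic scales set to the published model-assessed
  medians (PFS 6.2/4.8 months, OS 13.9/11.6 months). The shapes are **not
  identified by anything published in the main text**; we fix them once at
  1.8 (PFS) and 1.5 (OS, heavier tail) as field-typical values and do not
  revisit them. This is the single most consequential assumption in the
  fixture: with equal OS shapes across arms the incremental QALY gain works
  out near 0.17 rather than the published 0.36, roughly doubling the ICER.
  Users with access to the originally fitted parameters should overwrite
  `params$survival`.
* `placeholder` — literature-typical 2022 USD stand-ins for inputs whose
  published source tables are not redistributable here: administration fee
  ($144.70/infusion), disease management ($836.50/month), best supportive
  care ($1,600/month), terminal palliative care ($10,761.26 once),
  chemotherapy and second-line unit prices, and grade ≥3 adverse-event
  (anemia, neutropenia, thrombocytopenia — the events exceeding 5%
  incidence) costs, incidences and disutilities.

The YAML round trip (`write_params()` / `read_params()`) preserves all
tags, so a user can transcribe the real tables without touching code.

## Costing decisions

The model cycle is one month but treatment cycles are 21 days (induction)
or 28 days (durvalumab maintenance). Induction administrations are charged
on the model cycle containing their calendar day; maintenance is charged as
a monthly rate scaled by days-per-month over the treatment interval
(30.4375/21 or 30.4375/28), preserving dose intensity. Doses are linear in
mg at a body surface area of 1.86 m² with no vial-wastage rounding.
Induction and maintenance costs, plus disease management, scale with the
progression-free share; the progressed state carries second-line therapy
for the published uptake proportions (a 50:50 pembrolizumab:docetaxel
blend — the split is unreported, configurable) until death, best supportive
care for the remainder, and disease management. Terminal palliative care is
charged once to the fraction dying in each cycle. Adverse-event costs and
disutilities (held for one cycle) apply once, in the first cycle. The
chemotherapy backbone defaults to the non-squamous pathway
(cisplatin/pemetrexed with pemetrexed maintenance, the cost-dominant
pathway); the squamous fraction is configurable. Induction is four
chemotherapy cycles (the methods-text reading; a six-cycle encoding is a
one-line change to `regimen$ct_induction_cycles`).

## Sensitivity analysis

One-way: every non-fixed parameter at ±20% bounds (prices downward only),
full model re-run at each bound, ranked by ICER span. Probabilistic: 1,000
Monte Carlo draws, gamma for costs (shape 1/cv², scale mean·cv²) and beta
for utilities/proportions/incidences (method of moments, sd = 0.2·mean),
cv 0.2 mirroring the one-way ranges; survival parameters stay fixed in the
PSA, as the distribution assignment covers costs, proportions and
preference values. The acceptability curve evaluates
P(λ·ΔE − ΔC > 0) over λ from 0 to $300,000/QALY in $5,000 steps.

## What the synthetic data do and do not show

The generator draws event times from arm-specific log-logistic laws with
independent exponential censoring (monthly rate 0.01 in the study
configuration — a simple non-informative stand-in; real trial censoring is
administrative and wave-like), digitizes on a 0.25-month grid with 3-month
at-risk rows, and sizes arms at 338/337 patients. Passing the round-trip,
recovery and selection tests therefore shows the pipeline is faithful to
*KM-representable* information under clean conditions; it does not certify
digitization error from real figures, informative censoring, or
non-log-logistic truth. Problem sizes used in the tests (n = 300–2,000,
20 seeds, 1,000 PSA draws) were chosen to keep Monte Carlo error well below
the asserted tolerances.

## Numerical choices

* Event-count rounding in reconstruction: round-half-even on the running
  at-risk count; residual off-by-one allocations are absorbed into the
  censoring stream at the interval end (O(1/n) effect on the KM curve);
  larger residuals raise a reconciliation error naming the interval.
* Ties of events and censorings at one time: events first (standard KM
  convention, via `survival::survfit`).
* Optimizer failures: up to three jittered restarts; non-convergence is an
  error carrying the optimizer message, and `fit_all_families()` drops such
  candidates with a message rather than aborting the comparison.
* Degenerate inputs rejected with informative errors: all-censored data,
  fewer than 10 records, curves whose drops are impossible given the
  at-risk counts, ages beyond the life table, horizons not divisible by the
  cycle length.

## Known limitations

* The base-case fixture reproduces the published *verdict* (an ICER several
  times any plausible U.S. threshold, a flat-zero acceptability curve over
  $100–150k/QALY, and no rescue from the durvalumab price slide) but not
  the published point totals: with placeholder supportive-care costs and
  unidentified survival shapes the model gives ~$396k vs ~$180k and 1.14 vs
  0.97 QALYs (ICER ≈ $1.28M/QALY) against the published $352,291 vs
  $134,598 and 1.22 vs 0.87 (ICER $608,667.86). The published increments
  themselves illustrate rounding: $217,694/0.36 = $604,705.56, with the
  remaining gap to $608,667.86 due to unrounded internals.
* Because the fixture's incremental QALYs are smaller than published, the
  tornado ranks the PFS utility above the durvalumab price (the published
  tornado has the price first); the price-slide conclusion is unaffected.
* Second-line therapy is a stylized blended stream until death, not a
  time-limited course; societal costs, vial wastage and covariate
  heterogeneity are out of scope.
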