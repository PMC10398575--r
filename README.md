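# psmcea

Trial-based cost-effectiveness modelling for two-arm oncology regimens,
built around the question of whether adding a limited course of a CTLA-4
inhibitor (tremelimumab) and a PD-L1 inhibitor (durvalumab) to first-line
platinum chemotherapy (T+D+CT vs CT) is value for money in metastatic
non-small cell lung cancer from a U.S. payer perspective.

The package implements the whole analysis chain as reusable, tested
functions, with numbered driver scripts under `analysis/` telling the story
end to end.

## The model

**Evidence reconstruction.** Published survival evidence arrives as figures,
not data. `emulate_digitization()` mimics what a graph digitizer extracts
from a Kaplan–Meier plot (step-function read-offs plus the printed
numbers-at-risk row), and `reconstruct_ipd()` inverts that into pseudo
individual patient data: within each inter-risk-time interval it allocates
integer event and censoring counts so that the KM estimate of the output
matches the digitized curve and the implied number at risk matches the
printed row exactly. The reconstruction is deterministic.

**Extrapolation.** `fit_family()` fits seven parametric families
(exponential, Weibull, log-normal, log-logistic, gamma, generalized gamma,
Gompertz) to the reconstructed records by right-censored maximum likelihood;
`select_model()` picks the AIC minimizer (reporting BIC disagreements). The
log-logistic convention throughout is S(t) = 1 / (1 + (t/scale)^shape), so
the median equals the scale in months.

**Cohort model.** A three-state partitioned-survival model (progression-free
/ progressed / dead) on 1-month cycles over a 200-month horizon reads state
occupancy directly from the curves: p_PFS(t) = S_PFS(t), p_death(t) = 1 −
S_OS(t), progressed the difference, with extrapolated OS floored at period
life-table mortality (hazard rule h_eff = max(h_disease, h_background)) and
PFS capped at OS. Costs and QALYs accrue at cycle start (no half-cycle
correction) and discount at 3% per year. Regimen costing maps 21-day
treatment cycles onto the monthly grid by elapsed days; utilities are 0.673
(progression-free), 0.473 (progressed), 0 (dead), with grade ≥3
adverse-event costs and disutilities charged once in the first cycle. The
headline output is the incremental cost-effectiveness ratio
ICER = ΔCost / ΔQALY, judged against a $100,000–150,000/QALY
willingness-to-pay range.

**Uncertainty.** `tornado()` re-runs the model with one parameter at a time
at its bounds (±20%; drug prices slide downward only); `run_psa()` draws all
uncertain parameters jointly (gamma for costs, beta for utilities,
proportions and incidences, cv 0.2, method of moments) for 1,000 Monte Carlo
model runs, and `ceac()` turns the draws into a cost-effectiveness
acceptability curve via net monetary benefit.

A note on inputs: drug prices, utilities, dosing calendars, second-line
proportions and discounting are publication-reported; the supportive-care
and adverse-event cost inputs are literature-typical 2022 USD placeholders,
and the survival shapes are calibrated only to published medians. Every
parameter carries a `provenance` tag (`paper` / `derived` / `calibrated` /
`placeholder`) so the distinction is machine-readable; see the methods
vignette for what that implies about the numbers below.

## Worked example

```r
library(psmcea)

params <- base_case_fixture()
res <- run_model(params)   # calibrated curves, synthetic life table
print(res)
```

```
tdct         cost $396,272  QALYs 1.142  LY 2.048
ct           cost $180,428  QALYs 0.973  LY 1.767
incremental  cost $215,843  QALYs 0.169
ICER $1,276,803 per QALY (WTP $100,000-150,000: not cost-effective)
```

Reading: over a lifetime horizon the intensified arm costs an extra
~$216k and adds ~0.17 quality-adjusted life-years, i.e. roughly $1.28M per
QALY — an order of magnitude above the willingness-to-pay range, so the
combination is not cost-effective at these prices under this fixture (the
published analysis, using its own fitted survival curves and cost tables,
reports the same verdict at $608,667.86/QALY). One-way analysis:

```r
ow <- one_way(params, "drugs.durvalumab_per_admin")
ow$icer_low     # 1096110 — ICER at the bottom of the published price slide
```

Even at the lowest published durvalumab price the ICER stays far above
$150,000/QALY.

The full narrative lives in the numbered scripts:

```sh
Rscript analysis/01_simulate_trial.R    # trial-like data + digitized figures
Rscript analysis/02_reconstruct_ipd.R   # pseudo-IPD, fidelity <= 0.0012
Rscript analysis/03_fit_survival.R      # 7-family fits, AIC selection
Rscript analysis/04_base_case.R         # discounted totals and ICER
Rscript analysis/05_sensitivity.R       # tornado, 1,000-draw PSA, CEAC
```

Each writes its tables under `results/`.

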