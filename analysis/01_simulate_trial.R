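#!/usr/bin/env Rscript
# Stage 1 — emulate the published evidence base.
#
# Simulates a two-arm mNSCLC trial (immunochemotherapy vs chemotherapy)
# whose true PFS/OS follow the calibrated log-logistic laws, then emulates
# what a graph digitizer extracts from the published figures: Kaplan-Meier
# read-off coordinates on a fine grid plus the printed numbers-at-risk rows.
# Downstream stages see only the digitized artifacts, as a real analysis
# would.

suppressMessages(library(psmcea))

seed <- 2024
outdir <- "results/synthetic"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

params <- base_case_fixture()
sv <- params$survival
spec_tdct <- arm_spec("tdct",
                      sv$tdct$pfs$scale$value, sv$tdct$pfs$shape$value,
                      sv$tdct$os$scale$value, sv$tdct$os$shape$value,
                      n_patients = 338, censor_rate = 0.01)
spec_ct <- arm_spec("ct",
                    sv$ct$pfs$scale$value, sv$ct$pfs$shape$value,
                    sv$ct$os$scale$value, sv$ct$os$shape$value,
                    n_patients = 337, censor_rate = 0.01)

trial <- synthetic_trial(spec_tdct, spec_ct, seed = seed)

for (arm in names(trial$ipd)) {
  for (ep in c("pfs", "os")) {
    write_ipd(trial$ipd[[arm]][[ep]],
              file.path(outdir, sprintf("%s_%s_true_ipd.csv", arm, ep)))
    write_km_curve(trial$curves[[arm]][[ep]],
                   file.path(outdir, sprintf("%s_%s", arm, ep)))
  }
}
write_params(params, file.path(outdir, "base_case_params.yaml"))

cat("Simulated trial (seed", seed, "): 338 + 337 patients\n")
for (arm in names(trial$ipd)) {
  for (ep in c("pfs", "os")) {
    x <- trial$ipd[[arm]][[ep]]
    km <- km_estimator(x)
    cat(sprintf("  %-4s %-3s: %d events, KM median %.2f months\n",
                arm, toupper(ep), sum(x$event),
                min(km$time[km$survival <= 0.5])))
  }
}
cat("Digitized curves, at-risk tables, true IPD and the parameter file are in",
    outdir, "\n")
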