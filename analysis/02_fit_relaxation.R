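#!/usr/bin/env Rscript
# Step 2 — Prony-series fit of the simulated campaign.
#
# Pools the normalized relaxation traces of one donor (the fitting donor,
# as in the tissue study; the other donors are held out for comparison)
# and fits the three-branch reduced relaxation function by the
# stochastic-deterministic procedure.

suppressPackageStartupMessages(library(plantarQLV))

ds <- read_traces("results/dataset")
fit_donor <- "D2"  # the 8-sample donor
traces <- dataset_traces(ds[ds$donor_id == fit_donor, ], keep_meta = TRUE)

fit <- fit_prony(traces, fit_config(m = 3, seed = 7L))
print(fit)
write_fit_result(fit, "results/fit_prony3.json")

truth <- attr(ds, "truth")$ps
message(sprintf("true gamma: %s | fitted: %s",
                paste(round(truth$gamma, 3), collapse = " "),
                paste(round(fit$prony$gamma, 3), collapse = " ")))
message(sprintf("true tau:   %s | fitted: %s",
                paste(round(truth$tau, 2), collapse = " "),
                paste(round(fit$prony$tau, 2), collapse = " ")))
message("fit written to results/fit_prony3.json")
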