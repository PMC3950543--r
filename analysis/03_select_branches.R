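#!/usr/bin/env Rscript
# Step 3 — how many viscous branches does the relaxation need?
#
# Fits one to four branches to the same pooled traces and applies the
# parsimony rule (an extra branch must improve chi by at least 5%).

suppressPackageStartupMessages(library(plantarQLV))

ds <- read_traces("results/dataset")
traces <- dataset_traces(ds[ds$donor_id == "D2", ], keep_meta = TRUE)

sel <- select_model(traces, fit_config(seed = 7L))
print(sel)

tab <- data.frame(
  m = as.integer(names(sel$chi)),
  chi = sel$chi,
  gamma = vapply(sel$fits, function(f)
    paste(round(f$prony$gamma, 3), collapse = "/"), character(1)),
  tau_s = vapply(sel$fits, function(f)
    paste(round(f$prony$tau, 2), collapse = "/"), character(1)))
utils::write.csv(tab, "results/branch_selection.csv", row.names = FALSE)
message(sprintf("recommended branch count: %d -> results/branch_selection.csv",
                sel$recommended))
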