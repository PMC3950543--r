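#!/usr/bin/env Rscript
# Step 1 — virtual stress-relaxation campaign.
#
# Generates the 24-sample / 3-donor population with the reference material
# parameters, runs the consecutive relaxation protocol (120%/s ramp to 4, 6
# and 8% nominal strain, 240 s hold, full recovery between tests) with the
# default measurement-noise model, and writes one CSV per trace plus a
# provenance manifest.

suppressPackageStartupMessages(library(plantarQLV))

seed <- 20260928L
pop <- generate_population(seed = seed)
ds <- simulate_experiment(pop, relax_protocol(ramp = "true"), seed = seed + 1L)

dir.create("results", showWarnings = FALSE)
write_traces(ds, "results/dataset")

n_traces <- length(dataset_traces(ds))
message(sprintf("simulated %d traces (%d samples x 3 strain levels) -> results/dataset/",
                n_traces, nrow(pop)))
message(sprintf("normalized stress at 240 s, first trace: %.3f",
                {
                  tr <- dataset_traces(ds)[[1]]
                  tail(tr$stress_MPa, 1) / tr$stress_MPa[1]
                }))
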