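#!/usr/bin/env Rscript
# Step 5 — strain-rate dependence of the tensile response.
#
# Integrates constant-rate ramps to 6% nominal strain at four rates and
# compares secant moduli; also evaluates the ramp-neglect bound (stress
# deficit of the real 120%/s ramp vs an ideal step at 8% strain) and the
# terminal decay rate of the hold.

suppressPackageStartupMessages(library(plantarQLV))

hp <- ref_hyperelastic()
ps <- ref_prony(3)
rates <- c(0.006, 0.012, 0.024, 0.24)

curves <- lapply(rates, function(r) ramp_curve(hp, ps, r, 0.06))
sec <- vapply(curves, secant_modulus, numeric(1), strain = 0.06)
tab <- data.frame(rate_per_s = rates, secant_modulus_MPa = sec)
print(tab)
utils::write.csv(tab, "results/secant_moduli.csv", row.names = FALSE)

long <- do.call(rbind, lapply(seq_along(rates), function(i) {
  data.frame(rate_per_s = rates[i], stretch = 1 + curves[[i]]$strain,
             cauchy_stress_MPa = curves[[i]]$stress_MPa)
}))
utils::write.csv(long, "results/ramp_curves.csv", row.names = FALSE)

message(sprintf("secant-modulus difference, slowest vs fastest rate: %.1f%%",
                100 * (sec[4] - sec[1]) / sec[1]))

ramp <- integrate_history(hp, ps, function(t) pmin(0.08 * t / 0.067, 0.08),
                          t_end = 0.067, dt = 0.067 / 1000)
s_step <- elastic_axial_stress(hp, 1.08)$second_pk
message(sprintf("end-of-ramp stress deficit vs ideal step at 8%%: %.3f%%",
                100 * (s_step - ramp$stress_MPa[nrow(ramp)]) / s_step))
message(sprintf("normalized decay rate at 240 s: %.5f %%/s",
                relaxation_decay_rate(ps, 240)))
message(sprintf("residual normalized stress at 240 s: %.1f%%",
                100 * reduced_relaxation(ps, 240)))
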