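# Shared fixtures: closed-form step-relaxation traces with optional
# multiplicative measurement noise, built from the model itself so the
# generator doubles as the oracle in recovery tests.

make_step_traces <- function(ps, n = 1, cv = 0, scatter = 0, seed = 1,
                             strain = 0.06, hp = ref_hyperelastic(),
                             times = c(0, hold_time_grid())) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ps_i <- ps
      if (scatter > 0 && ps$m > 0) {
        g <- ps$gamma * exp(stats::rnorm(ps$m, 0, scatter))
        if (sum(g) > 1) g <- g * (0.995 / sum(g))
        ps_i <- prony_series(g, ps$tau)
      }
      tr <- step_relaxation(hp, ps_i, strain, times)
      if (cv > 0) {
        tr$stress_MPa <- tr$stress_MPa *
          (1 + stats::rnorm(nrow(tr), 0, cv))
      }
      tr
    })
  })
}

# Central finite difference of the strain energy along the incompressible
# uniaxial path: independent oracle for the analytic axial stress.
fd_nominal_stress <- function(hp, lam, h = 1e-7) {
  w <- function(l) strain_energy(hp, kinematics_from_stretch(l))
  (w(lam + h) - w(lam - h)) / (2 * h)
}
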