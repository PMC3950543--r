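test_that("reduced relaxation function matches direct Prony arithmetic", {
  ps3 <- ref_prony(3)
  expect_equal(reduced_relaxation(ps3, 0), 1)
  # long-time limit is 1 - sum(gamma)
  expect_equal(reduced_relaxation(ps3, 1e9), 1 - sum(ps3$gamma))
  expect_equal(1 - sum(ps3$gamma), 0.58)
  # direct evaluation at the end of the hold
  r240 <- 1 - 0.19 * (1 - exp(-240 / 1.00)) -
    0.11 * (1 - exp(-240 / 7.02)) - 0.12 * (1 - exp(-240 / 75.21))
  expect_equal(reduced_relaxation(ps3, 240), r240)
  expect_equal(r240, 0.5849, tolerance = 1e-4)

  ps1 <- ref_prony(1)
  expect_equal(reduced_relaxation(ps1, 6), 1 - 0.39 * (1 - exp(-1)))
  expect_equal(reduced_relaxation(ps1, 6), 0.75347, tolerance = 1e-5)

  expect_error(reduced_relaxation(ps3, -1), "non-negative")
})

test_that("R(t) properties hold for random Prony series", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      m <- sample(1:4, 1)
      g <- runif(m)
      g <- g / sum(g) * runif(1, 0.2, 1)
      tau <- 10^runif(m, -2, 3)
      ps <- prony_series(g, tau)
      tt <- sort(c(0, 10^seq(-3, 4, length.out = 50)))
      r <- reduced_relaxation(ps, tt)
      expect_equal(r[1], 1)
      expect_true(all(diff(r) <= 1e-15))
      expect_equal(reduced_relaxation(ps, 1e12), 1 - sum(g))
      expect_true(all(diff(ps$tau) > 0))  # sorted ascending
    }
  })
})

test_that("prony_series enforces its constraints", {
  expect_error(prony_series(c(0.5, 0.6), c(1, 10)), "exceed 1")
  expect_error(prony_series(1.2, 5), "0, 1")
  expect_error(prony_series(0.3, -2), "positive")
  expect_error(prony_series(c(0.3, 0.2), 5), "length")
  ps <- prony_series(c(0.1, 0.2), c(50, 2))  # gets sorted by tau
  expect_equal(ps$tau, c(2, 50))
  expect_equal(ps$gamma, c(0.2, 0.1))
  expect_equal(prony_series()$m, 0)
})

test_that("step relaxation is the reduced relaxation times the elastic stress", {
  hp <- ref_hyperelastic()
  ps <- ref_prony(3)
  times <- c(0, 0.1, 1, 10, 240)
  tr <- step_relaxation(hp, ps, 0.06, times)
  s_el <- elastic_axial_stress(hp, 1.06)$second_pk
  expect_equal(tr$stress_MPa[1], s_el)  # R(0) = 1
  expect_equal(tr$stress_MPa, reduced_relaxation(ps, times) * s_el)
  expect_equal(tr$stress_MPa[5], 0.584935 * s_el, tolerance = 1e-5)

  # no viscous branches: constant elastic trace
  tr0 <- step_relaxation(hp, prony_series(), 0.06, times)
  expect_equal(tr0$stress_MPa, rep(s_el, 5))
})

test_that("normalized step relaxation is strain-independent (quasi-linearity)", {
  hp <- ref_hyperelastic()
  ps <- ref_prony(3)
  times <- hold_time_grid()
  norm_tr <- function(strain) {
    tr <- step_relaxation(hp, ps, strain, times)
    tr$stress_MPa / tr$stress_MPa[1]
  }
  r4 <- norm_tr(0.04); r6 <- norm_tr(0.06); r8 <- norm_tr(0.08)
  expect_equal(r4, r6, tolerance = 1e-14)
  expect_equal(r6, r8, tolerance = 1e-14)
  expect_equal(r6, reduced_relaxation(ps, times) /
                 reduced_relaxation(ps, times[1]), tolerance = 1e-14)
})

test_that("history integrator reproduces the closed-form step solution", {
  hp <- ref_hyperelastic()
  ps <- ref_prony(3)
  times <- hold_time_grid(0.01, 240, n = 40)
  closed <- step_relaxation(hp, ps, 0.06, times)
  num <- integrate_history(hp, ps, function(t) 0.06, t_end = 240,
                           times = times)
  idx <- match(times, num$time_s)
  expect_equal(num$stress_MPa[idx], closed$stress_MPa, tolerance = 1e-12)

  # uniform fine grid as prescribed dt
  num2 <- integrate_history(hp, ps, function(t) 0.06, t_end = 10, dt = 0.01)
  expect_equal(num2$stress_MPa[num2$time_s == 10],
               step_relaxation(hp, ps, 0.06, 10)$stress_MPa,
               tolerance = 1e-3)
})

test_that("integrator error decays with step refinement on a ramp history", {
  hp <- ref_hyperelastic()
  ps <- ref_prony(3)
  hist_fun <- function(t) pmin(0.24 * t, 0.06)
  t_end <- 0.25
  ref <- integrate_history(hp, ps, hist_fun, t_end, dt = t_end / 16000)
  err <- vapply(c(100, 200, 400), function(n) {
    tr <- integrate_history(hp, ps, hist_fun, t_end, dt = t_end / n)
    abs(tr$stress_MPa[nrow(tr)] - ref$stress_MPa[nrow(ref)])
  }, numeric(1))
  expect_gt(err[1] / err[2], 1.8)
  expect_gt(err[2] / err[3], 1.8)
})

test_that("purely elastic limit and virgin state are exact", {
  hp <- ref_hyperelastic()
  hist_fun <- function(t) pmin(0.1 * t, 0.06)
  tr <- integrate_history(hp, prony_series(), hist_fun, t_end = 1, dt = 0.01)
  expect_equal(tr$stress_MPa,
               elastic_axial_stress(hp, 1 + tr$strain)$second_pk)
  # zero strain before loading gives exactly zero stress
  tr2 <- integrate_history(hp, ref_prony(3), function(t) 0, 1, dt = 0.1)
  expect_equal(tr2$stress_MPa, rep(0, nrow(tr2)))
  expect_error(integrate_history(hp, prony_series(), hist_fun, 1, dt = -1),
               "dt")
})

test_that("ramp curves stiffen with strain rate and approach the elastic limit", {
  hp <- ref_hyperelastic()
  ps <- ref_prony(3)
  rates <- c(0.006, 0.012, 0.024, 0.24)
  s06 <- vapply(rates, function(r) {
    secant_modulus(ramp_curve(hp, ps, r, 0.06), 0.06)
  }, numeric(1))
  expect_true(all(diff(s06) > 0))

  # near-instantaneous ramp approaches the pure elastic curve within 1%
  fast <- ramp_curve(hp, ps, 10, 0.06)
  s_el <- elastic_axial_stress(hp, 1.06)$cauchy
  expect_equal(secant_modulus(fast, 0.06), s_el / 0.06, tolerance = 0.01)
})

test_that("secant modulus interpolates stress over strain", {
  # linear material: returns E at every strain
  eps <- seq(0, 0.08, by = 0.002)
  lin <- stress_trace(seq_along(eps), eps, 120 * eps, "nominal")
  for (e in c(0.013, 0.04, 0.077)) {
    expect_equal(secant_modulus(lin, e), 120)
  }
  # elastic-only ramp at the reference parameters
  hp <- ref_hyperelastic()
  tr <- ramp_curve(hp, prony_series(), 0.06, 0.06)
  expect_equal(secant_modulus(tr, 0.06),
               elastic_axial_stress(hp, 1.06)$cauchy / 0.06,
               tolerance = 1e-6)
  # sampling-density consistency
  tr_coarse <- ramp_curve(hp, ref_prony(3), 0.024, 0.06, dt = 0.06 / 0.024 / 200)
  tr_fine <- ramp_curve(hp, ref_prony(3), 0.024, 0.06, dt = 0.06 / 0.024 / 2000)
  expect_equal(secant_modulus(tr_coarse, 0.05), secant_modulus(tr_fine, 0.05),
               tolerance = 1e-3)
  expect_error(secant_modulus(lin, 0.2), "outside")
})

test_that("trace decay rate matches the analytic Prony derivative", {
  hp <- ref_hyperelastic()
  # no viscous branches: zero decay everywhere
  tr0 <- step_relaxation(hp, prony_series(), 0.06, seq(0.01, 100, by = 0.01))
  expect_equal(decay_rate(tr0, 50), 0)

  gam <- 0.3; tau <- 5
  ps <- prony_series(gam, tau)
  tr <- step_relaxation(hp, ps, 0.06, seq(0.01, 20, by = 0.005))
  for (t in c(1, 3, 10)) {
    analytic <- 100 * (gam / tau) * exp(-t / tau) /
      reduced_relaxation(ps, 0.01)
    expect_equal(decay_rate(tr, t), analytic, tolerance = 1e-3)
  }
  expect_equal(decay_rate(tr, 3),
               relaxation_decay_rate(ps, 3) / reduced_relaxation(ps, 0.01),
               tolerance = 1e-3)
  expect_error(decay_rate(tr, 20), "inside")
  expect_error(decay_rate(tr, 0.01), "inside")
})

test_that("three-branch terminal decay rate is below 0.007 %/s", {
  ps <- ref_prony(3)
  expect_lt(relaxation_decay_rate(ps, 240), 0.007)
  # same conclusion from a simulated hold extending past 240 s
  tr <- step_relaxation(ref_hyperelastic(), ps, 0.06,
                        seq(230, 250, by = 0.5))
  expect_lt(decay_rate(normalize_trace(tr), 240) *
              reduced_relaxation(ps, 230), 0.007)
})
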