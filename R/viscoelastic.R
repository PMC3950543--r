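#' Prony series for the reduced relaxation function
#'
#' A set of viscous branches \eqn{(\gamma_i, \tau_i)} defining
#' \deqn{R(t) = 1 - \sum_i \gamma_i \left(1 - e^{-t/\tau_i}\right),}
#' where \eqn{\gamma_i \in (0, 1]} is the relative stiffness of the i-th
#' viscous process and \eqn{\tau_i > 0} its relaxation time in seconds.
#' Branches are stored sorted by ascending relaxation time; the empty series
#' (`m = 0`, purely elastic) is allowed.
#'
#' @param gamma Numeric vector of relative stiffnesses; each in (0, 1] and
#'   summing to at most 1.
#' @param tau Numeric vector of relaxation times (s), same length as `gamma`.
#' @return An object of class `prony_series` with fields `gamma`, `tau`, `m`.
#' @examples
#' ps <- prony_series(c(0.19, 0.11, 0.12), c(1.00, 7.02, 75.21))
#' reduced_relaxation(ps, c(0, 6, 240))
#' @export
prony_series <- function(gamma = numeric(), tau = numeric()) {
  stopifnot(is.numeric(gamma), is.numeric(tau))
  if (length(gamma) != length(tau)) {
    stop("`gamma` and `tau` must have the same length", call. = FALSE)
  }
  if (length(gamma) > 0) {
    if (any(!is.finite(gamma)) || any(gamma <= 0) || any(gamma > 1)) {
      stop("every `gamma` must lie in (0, 1]", call. = FALSE)
    }
    if (sum(gamma) > 1 + 1e-12) {
      stop("sum of `gamma` must not exceed 1", call. = FALSE)
    }
    if (any(!is.finite(tau)) || any(tau <= 0)) {
      stop("every `tau` must be positive (seconds)", call. = FALSE)
    }
    ord <- order(tau)
    gamma <- gamma[ord]
    tau <- tau[ord]
  }
  structure(list(gamma = as.numeric(gamma), tau = as.numeric(tau),
                 m = length(gamma)),
            class = "prony_series")
}

#' @export
print.prony_series <- function(x, ...) {
  cat(sprintf("Prony series with %d viscous branch(es)\n", x$m))
  if (x$m > 0) {
    print(data.frame(branch = seq_len(x$m), gamma = x$gamma, tau_s = x$tau),
          row.names = FALSE)
    cat(sprintf("  long-time residual 1 - sum(gamma) = %.4f\n",
                1 - sum(x$gamma)))
  }
  invisible(x)
}

#' Reference Prony series fitted to plantar aponeurosis relaxation data
#'
#' Published relative stiffnesses and relaxation times obtained by fitting
#' models with one to four viscous branches to stress-relaxation tests of
#' adult human plantar aponeurosis. The three-branch set is the one
#' retained in the characterization (short-, medium- and long-term
#' processes of order 1, 10 and 100 s).
#'
#' @param m Number of viscous branches, 1 to 4.
#' @return A `prony_series` object.
#' @export
ref_prony <- function(m = 3) {
  stopifnot(m %in% 1:4)
  switch(as.character(m),
    "1" = prony_series(0.39, 6.0),
    "2" = prony_series(c(0.25, 0.15), c(1.40, 39.87)),
    "3" = prony_series(c(0.19, 0.11, 0.12), c(1.00, 7.02, 75.21)),
    "4" = prony_series(c(0.03, 0.21, 0.11, 0.10),
                       c(0.10, 1.76, 23.87, 292.88)))
}

#' Reduced relaxation function
#'
#' Evaluates \eqn{R(t) = 1 - \sum_i \gamma_i (1 - e^{-t/\tau_i})}: the
#' stress during a constant-strain hold normalized to the stress at the
#' first instant of the hold. \eqn{R(0) = 1}, R is non-increasing, and
#' \eqn{R(\infty) = 1 - \sum_i \gamma_i}.
#'
#' @param ps A `prony_series` object.
#' @param t Time(s) since the start of the hold, in seconds, non-negative.
#' @return Dimensionless relaxation ratio, same length as `t`.
#' @export
reduced_relaxation <- function(ps, t) {
  stopifnot(inherits(ps, "prony_series"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("time `t` must be non-negative and finite", call. = FALSE)
  }
  if (ps$m == 0) return(rep(1, length(t)))
  1 - colSums(ps$gamma * (1 - exp(-outer(1 / ps$tau, t))))
}

#' Analytic decay rate of the reduced relaxation function
#'
#' Returns \eqn{-dR/dt \times 100 = 100 \sum_i (\gamma_i/\tau_i)
#' e^{-t/\tau_i}}, the normalized stress decay rate in percent of the
#' initial hold stress per second.
#'
#' @inheritParams reduced_relaxation
#' @return Decay rate in %/s, same length as `t`.
#' @export
relaxation_decay_rate <- function(ps, t) {
  stopifnot(inherits(ps, "prony_series"))
  if (!is.numeric(t) || any(t < 0)) {
    stop("time `t` must be non-negative", call. = FALSE)
  }
  if (ps$m == 0) return(rep(0, length(t)))
  100 * colSums((ps$gamma / ps$tau) * exp(-outer(1 / ps$tau, t)))
}

# -- stress traces -----------------------------------------------------------

#' Construct a stress trace
#'
#' A tidy record of one mechanical history: time, nominal strain and axial
#' stress, with the stress measure carried as an attribute.
#'
#' @param time_s Strictly increasing times (s).
#' @param strain Nominal strain at those times.
#' @param stress_MPa Axial stress (MPa).
#' @param measure Stress measure of the `stress_MPa` column.
#' @return A tibble of class `stress_trace` with attribute `measure`.
#' @export
stress_trace <- function(time_s, strain, stress_MPa,
                         measure = c("second_pk", "nominal", "cauchy")) {
  measure <- match.arg(measure)
  stopifnot(length(time_s) == length(strain),
            length(time_s) == length(stress_MPa))
  if (any(diff(time_s) <= 0)) {
    stop("`time_s` must be strictly increasing", call. = FALSE)
  }
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        strain = as.numeric(strain),
                        stress_MPa = as.numeric(stress_MPa))
  attr(out, "measure") <- measure
  class(out) <- c("stress_trace", class(out))
  out
}

#' Stress measure of a trace
#' @param trace A `stress_trace`.
#' @return One of `"second_pk"`, `"nominal"`, `"cauchy"`.
#' @export
trace_measure <- function(trace) {
  m <- attr(trace, "measure")
  if (is.null(m)) "second_pk" else m
}

#' Logarithmic sampling grid for a relaxation hold
#'
#' Log-spaced instants spanning the three time decades of the relaxation
#' process, augmented with the four reporting instants 0.1, 6, 72 and 240 s.
#'
#' @param t_min,t_max Hold window (s).
#' @param n Number of log-spaced points.
#' @param reporting Instants always included (those inside the window).
#' @return Sorted vector of unique times.
#' @export
hold_time_grid <- function(t_min = 0.01, t_max = 240, n = 60,
                           reporting = c(0.1, 6, 72, 240)) {
  g <- 10^seq(log10(t_min), log10(t_max), length.out = n)
  g <- sort(unique(c(g, reporting[reporting >= t_min & reporting <= t_max])))
  # collapse points that coincide to writing precision
  g[c(TRUE, diff(g) / g[-1] > 1e-9)]
}

#' Closed-form stress relaxation after an ideal step in strain
#'
#' Quasi-linear viscoelastic solution for an instantaneous stretch to
#' `1 + strain` held constant: \eqn{S(t) = R(t)\, S_e(\lambda)}. The
#' normalized trace \eqn{S(t)/S(0)} is independent of the strain level and
#' of the hyperelastic parameters (quasi-linearity).
#'
#' @param hp A `hyperelastic_params` object.
#' @param ps A `prony_series` object.
#' @param strain Nominal strain of the hold, non-negative.
#' @param times Hold times (s), non-negative, strictly increasing.
#' @param measure Stress measure for the output trace.
#' @return A `stress_trace`.
#' @export
step_relaxation <- function(hp, ps, strain, times = hold_time_grid(),
                            measure = "second_pk") {
  stopifnot(strain >= 0, all(times >= 0))
  measure <- match.arg(measure, .stress_measures)
  lam <- 1 + strain
  s0 <- elastic_axial_stress(hp, lam)[[measure]]
  stress_trace(times, rep(strain, length(times)),
               reduced_relaxation(ps, times) * s0, measure)
}

# Exact update of the viscous internal variables over one step with the
# elastic drive varying linearly in time:
#   Q_i' = -Q_i/tau_i + (gamma_i/tau_i) Se(t)
# gives Q_i(t+dt) = e*Q_i + gamma_i*Se_n*(1-e) + gamma_i*dSe*(1 - (tau/dt)(1-e)).
.advance_viscous <- function(q, ps, se_prev, se_next, dt) {
  if (ps$m == 0) return(q)
  e <- exp(-dt / ps$tau)
  dse <- se_next - se_prev
  q * e + ps$gamma * se_prev * (1 - e) +
    ps$gamma * dse * (1 - (ps$tau / dt) * (1 - e))
}

#' Integrate the viscoelastic response over an arbitrary strain history
#'
#' Advances the per-branch viscous internal stresses \eqn{Q_i} with an
#' exponential recursive scheme that is exact when the elastic drive is
#' linear within a step (and therefore exact during constant-strain holds).
#' The drive is the axial elastic second Piola-Kirchhoff stress with the
#' hydrostatic term eliminated by the zero-lateral-stress condition at
#' every instant; the total axial stress is \eqn{S = S_e - \sum_i Q_i}.
#' The material starts in the virgin state (\eqn{Q_i = 0}, zero stress
#' before loading).
#'
#' @param hp A `hyperelastic_params` object.
#' @param ps A `prony_series` object.
#' @param strain_history Function of time (s) returning nominal strain;
#'   `strain_history(0)` defines the start of loading.
#' @param t_end End time (s).
#' @param dt Uniform step size (s); ignored when `times` is supplied.
#' @param times Optional explicit, strictly increasing integration grid
#'   starting at 0; useful for log-spaced holds where the drive is constant
#'   and the update is exact for any step size.
#' @param measure Stress measure for the output trace.
#' @return A `stress_trace` sampled on the integration grid.
#' @export
integrate_history <- function(hp, ps, strain_history, t_end, dt = NULL,
                              times = NULL, measure = "second_pk") {
  measure <- match.arg(measure, .stress_measures)
  if (is.null(times)) {
    if (is.null(dt) || !is.numeric(dt) || dt <= 0) {
      stop("`dt` must be positive when `times` is not given", call. = FALSE)
    }
    times <- seq(0, t_end, by = dt)
    if (times[length(times)] < t_end) times <- c(times, t_end)
  } else {
    if (any(diff(times) <= 0)) {
      stop("`times` must be strictly increasing", call. = FALSE)
    }
    if (times[1] != 0) times <- c(0, times)
  }
  eps <- vapply(times, strain_history, numeric(1))
  if (any(eps < 0)) stop("negative strain in history", call. = FALSE)
  lam <- 1 + eps
  se <- elastic_axial_stress(hp, lam)$second_pk
  n <- length(times)
  if (ps$m > 0) {
    q <- rep(0, ps$m)  # virgin state
    qsum <- numeric(n)
    for (i in seq_len(n - 1)) {
      q <- .advance_viscous(q, ps, se[i], se[i + 1], times[i + 1] - times[i])
      qsum[i + 1] <- sum(q)
    }
    s <- se - qsum
  } else {
    s <- se
  }
  out <- convert_stress(s, lam, "second_pk", measure)
  stress_trace(times, eps, out, measure)
}

#' Constant-strain-rate tensile ramp
#'
#' Integrates a ramp at the given nominal strain rate up to the target
#' strain and reports the stress-stretch curve, by default in Cauchy
#' measure as conventional for rate-effect plots.
#'
#' @param hp A `hyperelastic_params` object.
#' @param ps A `prony_series` object.
#' @param strain_rate Nominal strain rate (1/s), positive.
#' @param target_strain Final nominal strain, positive.
#' @param dt Step size (s); defaults to 1/500 of the ramp duration.
#' @param measure Stress measure of the output.
#' @return A `stress_trace` covering the ramp.
#' @export
ramp_curve <- function(hp, ps, strain_rate, target_strain, dt = NULL,
                       measure = "cauchy") {
  if (!is.numeric(strain_rate) || strain_rate <= 0) {
    stop("`strain_rate` must be positive", call. = FALSE)
  }
  if (!is.numeric(target_strain) || target_strain <= 0) {
    stop("`target_strain` must be positive", call. = FALSE)
  }
  t_end <- target_strain / strain_rate
  if (is.null(dt)) dt <- t_end / 500
  integrate_history(hp, ps,
                    function(t) pmin(strain_rate * t, target_strain),
                    t_end = t_end, dt = dt, measure = measure)
}

#' Secant modulus of a stress-strain trace
#'
#' Stiffness at a given nominal strain measured as stress divided by
#' strain, with stress linearly interpolated between trace samples. The
#' stress measure is that of the trace.
#'
#' @param trace A `stress_trace` whose strain column spans the query.
#' @param strain Nominal strain at which to evaluate, within the trace range.
#' @return Secant modulus in MPa.
#' @export
secant_modulus <- function(trace, strain) {
  rng <- range(trace$strain)
  if (strain < rng[1] || strain > rng[2]) {
    stop(sprintf("strain %g outside trace range [%g, %g]",
                 strain, rng[1], rng[2]), call. = FALSE)
  }
  if (strain <= 0) stop("secant modulus needs positive strain", call. = FALSE)
  s <- stats::approx(trace$strain, trace$stress_MPa, xout = strain,
                     ties = "ordered")$y
  s / strain
}

#' Normalized stress decay rate from a relaxation trace
#'
#' Local finite-difference estimate of \eqn{-d(S/S(0))/dt \times 100} at
#' time `t` of a constant-strain hold, in percent of the initial hold
#' stress per second. Uses the two grid neighbors bracketing `t`; `t` must
#' therefore lie strictly inside the trace support.
#'
#' @param trace A `stress_trace` recorded during a hold.
#' @param t Time (s) strictly inside the trace's time range.
#' @return Decay rate in %/s.
#' @export
decay_rate <- function(trace, t) {
  tt <- trace$time_s
  if (t <= tt[1] || t >= tt[length(tt)]) {
    stop("`t` must lie strictly inside the trace support (neighbors needed)",
         call. = FALSE)
  }
  s <- trace$stress_MPa / trace$stress_MPa[1]
  i <- findInterval(t, tt)
  # central difference over the bracketing points around t
  i0 <- max(i - 1, 1)
  i1 <- min(i + 1, length(tt))
  if (tt[i] == t && i > 1 && i < length(tt)) {
    i0 <- i - 1; i1 <- i + 1
  }
  -(s[i1] - s[i0]) / (tt[i1] - tt[i0]) * 100
}
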