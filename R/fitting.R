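#' Configuration of the stress-relaxation fitting procedure
#'
#' Controls the two-stage (stochastic then deterministic) minimization of
#' the relative-residual error functional
#' \deqn{\chi = \left\{\frac{1}{N}\sum_{i=1}^{N}
#'   \left[1 - \frac{R^{exp}(t_i)}{R(\eta, t_i)}\right]^2\right\}^{1/2}}
#' over the Prony parameter vector \eqn{\eta = (\gamma_1, \tau_1, \ldots)}.
#'
#' @param m Number of viscous branches to fit (1-4).
#' @param eval_times The N evaluation instants \eqn{t_i} (s); default 40
#'   log-spaced points in [0.05, 240] s, covering each relaxation decade
#'   evenly. Must satisfy `N >= 2 m` for identifiability.
#' @param tau_bounds Search interval for relaxation times (s), explored on
#'   a log scale.
#' @param n_global Iterations of the simulated-annealing global stage.
#' @param n_restarts Independent annealing chains; the best is refined.
#' @param local_maxit,local_reltol Nelder-Mead refinement budget/tolerance.
#' @param seed Integer seed making the whole fit reproducible.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(m = 3,
                       eval_times = 10^seq(log10(0.05), log10(240),
                                           length.out = 40),
                       tau_bounds = c(1e-2, 1e3),
                       n_global = 1200,
                       n_restarts = 2,
                       local_maxit = 4000,
                       local_reltol = 1e-12,
                       seed = 1L) {
  stopifnot(m %in% 1:4, length(tau_bounds) == 2, all(tau_bounds > 0),
            tau_bounds[1] < tau_bounds[2], n_global >= 1, n_restarts >= 1)
  if (length(eval_times) < 2 * m) {
    stop("need at least 2*m evaluation instants for identifiability",
         call. = FALSE)
  }
  if (any(eval_times <= 0)) stop("eval_times must be positive", call. = FALSE)
  structure(list(m = as.integer(m), eval_times = sort(eval_times),
                 tau_bounds = tau_bounds, n_global = as.integer(n_global),
                 n_restarts = as.integer(n_restarts),
                 local_maxit = as.integer(local_maxit),
                 local_reltol = local_reltol, seed = as.integer(seed)),
            class = "fit_config")
}

#' Normalize a relaxation trace to its initial hold stress
#'
#' Divides the stress column by the stress at the first hold instant,
#' producing the experimental relaxation ratio
#' \eqn{R^{exp}(t) = S^{exp}(t)/S^{exp}(0)}. Scale-invariant: traces
#' differing by a positive factor normalize identically.
#'
#' @param trace A `stress_trace` recorded during a constant-strain hold.
#' @return A `stress_trace` whose first stress value is 1 (dimensionless).
#' @export
normalize_trace <- function(trace) {
  s0 <- trace$stress_MPa[1]
  if (!is.finite(s0) || s0 <= 0) {
    stop("initial hold stress must be positive to normalize", call. = FALSE)
  }
  out <- trace
  out$stress_MPa <- trace$stress_MPa / s0
  out
}

# Interpolate a normalized trace at the evaluation instants, in log time
# (the traces are sampled on a log grid): cubic spline through the samples,
# linear for very short traces. Instants outside the support yield NA.
.interp_ratio <- function(trace, eval_times) {
  x <- log(pmax(trace$time_s, 1e-300))
  y <- trace$stress_MPa
  xo <- log(eval_times)
  inside <- xo >= x[1] & xo <= x[length(x)]
  out <- rep(NA_real_, length(xo))
  if (any(inside)) {
    out[inside] <- if (length(x) >= 4) {
      stats::spline(x, y, xout = xo[inside], method = "fmm",
                    ties = "ordered")$y
    } else {
      stats::approx(x, y, xout = xo[inside], ties = "ordered")$y
    }
  }
  out
}

# Pool traces into one mean experimental ratio per evaluation instant.
.pooled_ratio <- function(traces, eval_times) {
  if (inherits(traces, "stress_trace")) traces <- list(traces)
  if (inherits(traces, "relaxation_dataset") || (is.data.frame(traces) &&
      all(c("sample_id", "strain_level") %in% names(traces)))) {
    traces <- dataset_traces(traces)
  }
  mat <- vapply(traces,
                function(tr) .interp_ratio(normalize_trace(tr), eval_times),
                numeric(length(eval_times)))
  r <- rowMeans(as.matrix(mat))
  if (any(!is.finite(r))) {
    stop("evaluation instants outside the support of the traces",
         call. = FALSE)
  }
  r
}

#' Relative-residual error functional between model and data
#'
#' Root mean square of the relative residuals
#' \eqn{1 - R^{exp}(t_i)/R(\eta, t_i)} over the evaluation instants.
#' Multiple traces are pooled by averaging their normalized ratios at each
#' instant before comparison.
#'
#' @param ps A `prony_series` (the model \eqn{\eta}).
#' @param traces One `stress_trace`, a list of them, or a
#'   `relaxation_dataset`; normalized internally.
#' @param eval_times Evaluation instants (s).
#' @return Dimensionless error \eqn{\chi \ge 0}.
#' @export
chi_error <- function(ps, traces, eval_times) {
  r_exp <- .pooled_ratio(traces, eval_times)
  r_mod <- reduced_relaxation(ps, eval_times)
  if (any(r_mod <= 0)) {
    stop("model relaxation ratio must stay positive at the evaluation times",
         call. = FALSE)
  }
  sqrt(mean((1 - r_exp / r_mod)^2))
}

# -- parameter transforms ----------------------------------------------------
# gamma: softmax-style bijection onto the open simplex interior
#   gamma_i = exp(z_i) / (1 + sum_j exp(z_j))      => gamma_i > 0, sum < 1
# tau: logistic squash of log tau into the log bounds => positive, bounded
.theta_to_gt <- function(theta, m, tau_bounds) {
  z <- pmin(theta[seq_len(m)], 40)
  u <- theta[m + seq_len(m)]
  ez <- exp(z)
  gamma <- pmax(ez / (1 + sum(ez)), 1e-12)  # guard exp underflow
  lo <- log(tau_bounds[1]); hi <- log(tau_bounds[2])
  tau <- exp(lo + (hi - lo) * stats::plogis(u))
  list(gamma = gamma, tau = tau)
}

.theta_to_ps <- function(theta, m, tau_bounds) {
  gt <- .theta_to_gt(theta, m, tau_bounds)
  prony_series(gt$gamma, gt$tau)
}

.ps_to_theta <- function(gamma, tau, tau_bounds) {
  s <- sum(gamma)
  if (s >= 0.999) gamma <- gamma * (0.999 / s)
  z <- log(gamma / (1 - sum(gamma)))
  lo <- log(tau_bounds[1]); hi <- log(tau_bounds[2])
  f <- (log(pmin(pmax(tau, tau_bounds[1] * 1.001),
                 tau_bounds[2] * 0.999)) - lo) / (hi - lo)
  c(z, stats::qlogis(f))
}

.chi_theta <- function(theta, m, tau_bounds, r_exp, eval_times) {
  gt <- .theta_to_gt(theta, m, tau_bounds)
  r_mod <- 1 - colSums(gt$gamma * (1 - exp(-outer(1 / gt$tau, eval_times))))
  sqrt(mean((1 - r_exp / r_mod)^2))
}

# Stochastic initialization: draw relaxation-time ladders log-uniformly and
# solve the relative stiffnesses by linear least squares on the absolute
# residual (R is linear in gamma at fixed tau), projected onto the simplex.
.random_starts <- function(r_exp, eval_times, m, tau_bounds, k_draws = 150) {
  lo <- log10(tau_bounds[1]); hi <- log10(tau_bounds[2])
  starts <- vector("list", k_draws)
  for (k in seq_len(k_draws)) {
    tau <- sort(10^stats::runif(m, lo, hi))
    a <- 1 - exp(-outer(eval_times, 1 / tau))
    g <- tryCatch(qr.solve(a, 1 - r_exp), error = function(e) rep(0.3 / m, m))
    g <- pmin(pmax(g, 1e-4), 0.99)
    if (sum(g) > 0.99) g <- g * (0.99 / sum(g))
    r_mod <- 1 - colSums(g * (1 - exp(-outer(1 / tau, eval_times))))
    starts[[k]] <- list(gamma = g, tau = tau,
                        chi = sqrt(mean((1 - r_exp / r_mod)^2)))
  }
  starts[order(vapply(starts, `[[`, numeric(1), "chi"))]
}

# One seeded simulated-annealing chain with geometric cooling.
.anneal <- function(theta0, obj, n_iter) {
  chi0 <- obj(theta0)
  t0 <- max(chi0, 1e-3)
  cool <- (1e-4)^(1 / n_iter)
  theta <- theta0; chi <- chi0
  best <- theta0; best_chi <- chi0
  temp <- t0
  k <- length(theta0)
  for (i in seq_len(n_iter)) {
    step <- 0.02 + 0.6 * (temp / t0)^0.4
    cand <- theta + stats::rnorm(k, 0, step)
    chi_c <- obj(cand)
    if (chi_c < chi || stats::runif(1) < exp((chi - chi_c) / temp)) {
      theta <- cand; chi <- chi_c
      if (chi < best_chi) { best <- theta; best_chi <- chi }
    }
    temp <- temp * cool
  }
  list(theta = best, chi = best_chi)
}

# Nelder-Mead polish, repeated until no further improvement.
.polish <- function(theta, obj, maxit, reltol) {
  chi_prev <- obj(theta)
  conv <- FALSE
  for (round in 1:3) {
    fit <- stats::optim(theta, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    theta <- fit$par
    conv <- fit$convergence == 0
    if (chi_prev - fit$value < 1e-14) { chi_prev <- fit$value; break }
    chi_prev <- fit$value
  }
  list(theta = theta, chi = chi_prev, converged = conv)
}

#' Fit a Prony series to stress-relaxation data
#'
#' Two-stage stochastic-deterministic minimization of [chi_error()]:
#' seeded simulated-annealing chains explore relaxation times on a log
#' scale and relative stiffnesses on the simplex \eqn{\sum\gamma_i \le 1};
#' the best chain is refined by derivative-free Nelder-Mead. The result is
#' deterministic given the configuration seed, and the returned branches
#' are sorted by ascending relaxation time.
#'
#' @param traces One `stress_trace`, a list of them, or a
#'   `relaxation_dataset` of constant-strain holds (raw stresses are fine;
#'   normalization is internal).
#' @param cfg A [fit_config()].
#' @param start Optional `prony_series` used as an additional warm start.
#' @return An object of class `fit_result`: fields `prony`, `chi`, `m`,
#'   `seed`, `n_restarts_used`, `converged`, `config`.
#' @export
fit_prony <- function(traces, cfg = fit_config(), start = NULL) {
  stopifnot(inherits(cfg, "fit_config"))
  r_exp <- .pooled_ratio(traces, cfg$eval_times)
  obj <- function(theta) .chi_theta(theta, cfg$m, cfg$tau_bounds,
                                    r_exp, cfg$eval_times)
  m <- cfg$m
  res <- withr::with_seed(cfg$seed, {
    starts <- .random_starts(r_exp, cfg$eval_times, m, cfg$tau_bounds)
    cands <- list()
    for (r in seq_len(cfg$n_restarts)) {
      s <- starts[[min(r, length(starts))]]
      theta0 <- .ps_to_theta(s$gamma, s$tau, cfg$tau_bounds)
      cands[[r]] <- .anneal(theta0, obj, cfg$n_global)
    }
    if (!is.null(start)) {
      stopifnot(inherits(start, "prony_series"), start$m == m)
      th <- .ps_to_theta(start$gamma, start$tau, cfg$tau_bounds)
      cands[[length(cands) + 1]] <- list(theta = th, chi = obj(th))
    }
    ord <- order(vapply(cands, `[[`, numeric(1), "chi"))
    polished <- lapply(cands[ord[seq_len(min(2, length(cands)))]],
                       function(cand) .polish(cand$theta, obj,
                                              cfg$local_maxit,
                                              cfg$local_reltol))
    if (!is.null(start)) {
      th <- .ps_to_theta(start$gamma, start$tau, cfg$tau_bounds)
      polished[[length(polished) + 1]] <-
        .polish(th, obj, cfg$local_maxit, cfg$local_reltol)
    }
    polished[[which.min(vapply(polished, `[[`, numeric(1), "chi"))]]
  })
  structure(list(
    prony = .theta_to_ps(res$theta, m, cfg$tau_bounds),
    chi = res$chi,
    m = m,
    seed = cfg$seed,
    n_restarts_used = cfg$n_restarts,
    converged = res$converged,
    config = cfg
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Prony fit (m = %d): chi = %.3e, seed = %d%s\n", x$m, x$chi,
              x$seed, if (x$converged) "" else " [not converged]"))
  print(x$prony)
  invisible(x)
}

#' Select the number of viscous branches
#'
#' Fits models with increasing branch counts, warm-starting each count from
#' the previous solution plus one weak branch so the error is non-increasing
#' in m, and recommends the most parsimonious model: the smallest m whose
#' error is already negligible (below `chi_floor`) or whose successor
#' improves the error by less than `rel_improve`.
#'
#' @param traces As in [fit_prony()].
#' @param cfg Base [fit_config()]; its `m` is overridden per candidate.
#' @param m_range Candidate branch counts (ascending), default 1:4.
#' @param rel_improve Relative improvement below which an extra branch is
#'   judged marginal (default 5%).
#' @param chi_floor Error below which a model is considered to have
#'   explained the data to numerical accuracy.
#' @return An object of class `model_selection`: list with `fits` (one
#'   `fit_result` per m), `chi` (named vector), `recommended`.
#' @export
select_model <- function(traces, cfg = fit_config(), m_range = 1:4,
                         rel_improve = 0.05, chi_floor = 1e-4) {
  stopifnot(length(m_range) >= 1, all(diff(m_range) > 0))
  fits <- list()
  prev <- NULL
  for (m in m_range) {
    cfg_m <- cfg
    cfg_m$m <- as.integer(m)
    warm <- NULL
    if (!is.null(prev) && prev$m == m - 1) {
      gap_tau <- .widest_gap_tau(prev$prony, cfg$tau_bounds)
      warm <- prony_series(c(prev$prony$gamma, 1e-8),
                           c(prev$prony$tau, gap_tau))
    }
    fit <- fit_prony(traces, cfg_m, start = warm)
    # warm start guarantees chi(m) <= chi(m-1) up to the polish tolerance
    if (!is.null(prev) && fit$chi > prev$chi) {
      r_exp <- .pooled_ratio(traces, cfg_m$eval_times)
      obj <- function(theta) .chi_theta(theta, m, cfg_m$tau_bounds,
                                        r_exp, cfg_m$eval_times)
      th <- .ps_to_theta(warm$gamma, warm$tau, cfg_m$tau_bounds)
      pol <- .polish(th, obj, cfg_m$local_maxit, cfg_m$local_reltol)
      if (pol$chi < fit$chi) {
        fit$prony <- .theta_to_ps(pol$theta, m, cfg_m$tau_bounds)
        fit$chi <- pol$chi
        fit$converged <- pol$converged
      }
    }
    fits[[as.character(m)]] <- fit
    prev <- fit
  }
  chis <- vapply(fits, `[[`, numeric(1), "chi")
  recommended <- m_range[length(m_range)]
  for (i in seq_along(m_range)) {
    if (chis[i] < chi_floor) { recommended <- m_range[i]; break }
    if (i < length(m_range)) {
      if ((chis[i] - chis[i + 1]) / chis[i] < rel_improve) {
        recommended <- m_range[i]
        break
      }
    }
  }
  structure(list(fits = fits, chi = chis, recommended = recommended),
            class = "model_selection")
}

# Midpoint (log scale) of the widest gap in the current relaxation-time
# ladder, bounds included: a sensible location for a new weak branch.
.widest_gap_tau <- function(ps, tau_bounds) {
  pts <- sort(unique(c(log(tau_bounds[1]), log(ps$tau), log(tau_bounds[2]))))
  gaps <- diff(pts)
  i <- which.max(gaps)
  exp((pts[i] + pts[i + 1]) / 2)
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Branch-count selection\n")
  print(data.frame(m = as.integer(names(x$chi)), chi = x$chi),
        row.names = FALSE)
  cat(sprintf("recommended m = %d\n", x$recommended))
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' Writes the fitted branches, the error and the full configuration echo
#' (evaluation grid, bounds, seeds) so the fit can be regenerated.
#'
#' @param fit A `fit_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(list(
    prony = list(gamma = fit$prony$gamma, tau_s = fit$prony$tau),
    chi = fit$chi, m = fit$m, seed = fit$seed,
    n_restarts_used = fit$n_restarts_used, converged = fit$converged,
    config = list(eval_times = fit$config$eval_times,
                  tau_bounds = fit$config$tau_bounds,
                  n_global = fit$config$n_global,
                  n_restarts = fit$config$n_restarts)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
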