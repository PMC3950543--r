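#' Hyperelastic parameter set for fiber-reinforced ground matrix
#'
#' Bundles the three constitutive parameters of the transversely isotropic
#' hyperelastic strain-energy function used for plantar aponeurosis tissue:
#' a neo-Hookean ground matrix term \eqn{(\mu/2)(\tilde I_1 - 3)} and an
#' exponential fiber term active only in tension,
#' \deqn{\tilde W_{fib} = \frac{k}{2\alpha}\left[e^{\alpha\langle\tilde I_4-1\rangle}
#'   - \alpha\langle\tilde I_4-1\rangle - 1\right].}
#'
#' @param mu Shear-like stiffness of the ground matrix at small strain (MPa),
#'   must be positive.
#' @param k Stress-like fiber stiffness scale (MPa), must be non-negative.
#' @param alpha Dimensionless fiber nonlinearity exponent, must be positive.
#'
#' @return An object of class `hyperelastic_params`.
#' @examples
#' hp <- hyperelastic_params(mu = 14.449, k = 254.02, alpha = 10.397)
#' elastic_axial_stress(hp, 1.06)
#' @export
hyperelastic_params <- function(mu, k, alpha) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (mu <= 0) stop("`mu` must be positive (MPa)", call. = FALSE)
  if (k < 0) stop("`k` must be non-negative (MPa)", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  structure(list(mu = mu, k = k, alpha = alpha),
            class = "hyperelastic_params")
}

#' @export
print.hyperelastic_params <- function(x, ...) {
  cat("Transversely isotropic hyperelastic parameters\n")
  cat(sprintf("  mu    = %g MPa (ground matrix shear stiffness)\n", x$mu))
  cat(sprintf("  k     = %g MPa (fiber stiffness scale)\n", x$k))
  cat(sprintf("  alpha = %g (fiber nonlinearity exponent)\n", x$alpha))
  invisible(x)
}

#' Reference hyperelastic parameters for adult plantar aponeurosis
#'
#' Parameter triple obtained in the literature by fitting the fiber-reinforced
#' hyperelastic model to elastic tensile response data of adult human plantar
#' aponeurosis; used as the default elastic backbone of the viscoelastic
#' simulations in this package.
#'
#' @return A `hyperelastic_params` object with mu = 14.449 MPa,
#'   k = 254.02 MPa, alpha = 10.397.
#' @export
ref_hyperelastic <- function() {
  hyperelastic_params(mu = 14.449, k = 254.02, alpha = 10.397)
}

#' Incompressible uniaxial kinematics from the axial stretch
#'
#' Builds the kinematic state of an incompressible, transversely isotropic
#' material point stretched along the fiber axis. With \eqn{J = 1} the two
#' transverse stretches equal \eqn{\lambda^{-1/2}} and the modified
#' invariants reduce to \eqn{\tilde I_1 = \lambda^2 + 2/\lambda},
#' \eqn{\tilde I_4 = \lambda^2} (fibers aligned with the loading axis).
#'
#' @param lam Axial stretch, positive. May be a vector.
#' @return An object of class `kinematic_state` with fields `lam`, `lam_t`,
#'   `J`, `I1`, `I4`.
#' @export
kinematics_from_stretch <- function(lam) {
  if (!is.numeric(lam) || any(!is.finite(lam)) || any(lam <= 0)) {
    stop("stretch `lam` must be positive and finite", call. = FALSE)
  }
  structure(list(
    lam = lam,
    lam_t = lam^(-0.5),
    J = rep(1, length(lam)),
    I1 = lam^2 + 2 / lam,
    I4 = lam^2
  ), class = "kinematic_state")
}

#' Strain-energy density of the fiber-reinforced material
#'
#' Evaluates \eqn{\tilde W_{mat}(\tilde I_1) + \tilde W_{fib}(\tilde I_4)}.
#' The volumetric term contributes nothing at \eqn{J = 1}. The fiber term
#' uses the tension switch \eqn{\langle x\rangle = \max(x, 0)}: shortened
#' fibers (\eqn{\tilde I_4 \le 1}) store no energy.
#'
#' @param hp A `hyperelastic_params` object.
#' @param ks A `kinematic_state` object, e.g. from [kinematics_from_stretch()].
#' @return Energy density in MPa (vectorized over the state).
#' @export
strain_energy <- function(hp, ks) {
  stopifnot(inherits(hp, "hyperelastic_params"),
            inherits(ks, "kinematic_state"))
  e4 <- pmax(ks$I4 - 1, 0)
  w_mat <- (hp$mu / 2) * (ks$I1 - 3)
  w_fib <- if (hp$k == 0) 0 else
    (hp$k / (2 * hp$alpha)) * (exp(hp$alpha * e4) - hp$alpha * e4 - 1)
  w_mat + w_fib
}

#' Axial elastic stress under incompressible uniaxial tension
#'
#' Closed-form axial stress with the hydrostatic pressure eliminated by the
#' zero-lateral-stress condition. In Cauchy measure
#' \deqn{\sigma(\lambda) = \mu(\lambda^2 - 1/\lambda)
#'   + k\,\lambda^2\,[e^{\alpha\langle\lambda^2-1\rangle} - 1],}
#' which equals \eqn{\lambda\, dW/d\lambda} of [strain_energy()] on the
#' incompressible uniaxial path. All three stress measures are returned.
#'
#' @param hp A `hyperelastic_params` object.
#' @param lam Axial stretch, positive (vectorized).
#' @return An object of class `stress_value`: list with fields `lam`,
#'   `second_pk`, `nominal`, `cauchy` (MPa).
#' @export
elastic_axial_stress <- function(hp, lam) {
  stopifnot(inherits(hp, "hyperelastic_params"))
  if (!is.numeric(lam) || any(!is.finite(lam)) || any(lam <= 0)) {
    stop("stretch `lam` must be positive and finite", call. = FALSE)
  }
  e4 <- pmax(lam^2 - 1, 0)
  cauchy <- hp$mu * (lam^2 - 1 / lam) + hp$k * lam^2 * (exp(hp$alpha * e4) - 1)
  structure(list(
    lam = lam,
    second_pk = cauchy / lam^2,
    nominal = cauchy / lam,
    cauchy = cauchy
  ), class = "stress_value")
}

.stress_measures <- c("second_pk", "nominal", "cauchy")

#' Convert between stress measures at unit volume ratio
#'
#' At \eqn{J = 1} the axial second Piola-Kirchhoff stress \eqn{S}, nominal
#' (first Piola-Kirchhoff) stress \eqn{P} and Cauchy stress \eqn{\sigma}
#' are related by \eqn{P = \lambda S} and \eqn{\sigma = \lambda^2 S}.
#'
#' @param value Scalar or vector stress (MPa).
#' @param lam Axial stretch at which the value is expressed.
#' @param from,to Stress measures, one of `"second_pk"`, `"nominal"`,
#'   `"cauchy"`.
#' @return The converted stress.
#' @export
convert_stress <- function(value, lam, from, to) {
  if (!is.numeric(lam) || any(lam <= 0)) {
    stop("stretch `lam` must be positive", call. = FALSE)
  }
  from <- match.arg(from, .stress_measures)
  to <- match.arg(to, .stress_measures)
  fac <- function(measure) switch(measure,
    second_pk = 1, nominal = lam, cauchy = lam^2)
  value / fac(from) * fac(to)
}
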