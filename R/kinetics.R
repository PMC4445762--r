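#' Patient-specific growth kinetics
#'
#' Bundles the two hallmark parameters of the Proliferation-Invasion (PI)
#' model — the net invasion (dispersal) rate `D` and the net proliferation
#' rate `rho` — together with the tissue carrying capacity `K`. The PI model
#' describes the tumor cell density \eqn{c(\mathbf{x}, t)} by
#' \deqn{\partial c/\partial t = \nabla\cdot(D \nabla c) + \rho c (1 - c/K),}
#' whose long-time behaviour is a traveling front invading at velocity
#' \eqn{v = 2\sqrt{D\rho}} with gradient (e-folding) length
#' \eqn{\lambda = \sqrt{D/\rho}}.
#'
#' @param D Net invasion rate, mm^2/year. Must be positive.
#' @param rho Net proliferation rate, 1/year. Must be positive.
#' @param K Carrying capacity, cells/mm^3. Must be positive. The default is a
#'   conventional order of magnitude for packed glioma cells; every quantity
#'   the package reports is invariant to its absolute value because densities
#'   enter only as fractions of `K`.
#' @return An object of class `pi_kinetics`: a named list with elements `D`,
#'   `rho`, `K`.
#' @examples
#' k <- kinetics(D = 25, rho = 16)
#' front_velocity(k)   # 40 mm/year
#' gradient_length(k)  # 1.25 mm
#' rho_over_D(k)       # 0.64 per mm^2
#' @export
kinetics <- function(D, rho, K = 1e5) {
  stopifnot(is.numeric(D), length(D) == 1, is.finite(D), D > 0)
  stopifnot(is.numeric(rho), length(rho) == 1, is.finite(rho), rho > 0)
  stopifnot(is.numeric(K), length(K) == 1, is.finite(K), K > 0)
  structure(list(D = D, rho = rho, K = K), class = "pi_kinetics")
}

#' @export
print.pi_kinetics <- function(x, ...) {
  cat("<PI kinetics>\n")
  cat(sprintf("  D   = %g mm^2/yr   rho = %g /yr   K = %g cells/mm^3\n",
              x$D, x$rho, x$K))
  cat(sprintf("  velocity 2*sqrt(D*rho) = %.4g mm/yr   gradient length sqrt(D/rho) = %.4g mm   rho/D = %.4g /mm^2\n",
              front_velocity(x), gradient_length(x), rho_over_D(x)))
  invisible(x)
}

#' Asymptotic front velocity of the PI model
#'
#' The Fisher-KPP traveling-wave speed \eqn{v = 2\sqrt{D\rho}} (mm/year): the
#' slope of the linear radius-versus-time growth the model predicts on
#' imaging.
#'
#' @param x A [kinetics()] object.
#' @return Velocity in mm/year.
#' @export
front_velocity <- function(x) {
  stopifnot(inherits(x, "pi_kinetics"))
  2 * sqrt(x$D * x$rho)
}

#' Gradient length of the invading front
#'
#' The e-folding length \eqn{\lambda = \sqrt{D/\rho}} (mm) of the leading
#' edge of the traveling wave; diffuse tumors have long gradient lengths,
#' nodular tumors short ones.
#'
#' @inheritParams front_velocity
#' @return Gradient length in mm.
#' @export
gradient_length <- function(x) {
  stopifnot(inherits(x, "pi_kinetics"))
  sqrt(x$D / x$rho)
}

#' Aggressiveness ratio rho/D
#'
#' The relative-invasiveness ratio \eqn{\rho/D} (1/mm^2). High values
#' indicate nodular, proliferation-dominated disease; low values indicate
#' diffuse, invasion-dominated disease. The ratio is dimensionally a
#' reciprocal area, so it is invariant to any common rescaling of the time
#' unit of `D` and `rho`.
#'
#' @param x A [kinetics()] object, or a numeric vector of `D` values.
#' @param rho When `x` is numeric, the matching numeric vector of `rho`
#'   values (1/year).
#' @return rho/D in 1/mm^2, vectorised in the numeric form.
#' @export
rho_over_D <- function(x, rho = NULL) {
  if (inherits(x, "pi_kinetics")) return(x$rho / x$D)
  stopifnot(is.numeric(x), is.numeric(rho), all(x > 0), all(rho > 0))
  rho / x
}

#' Exact logistic growth reference solution
#'
#' Closed-form solution of the proliferation term alone,
#' \eqn{dc/dt = \rho c (1 - c/K)}:
#' \deqn{c(t) = \frac{K c_0 e^{\rho t}}{K + c_0 (e^{\rho t} - 1)}.}
#' This is the spatially homogeneous (`D` \eqn{\to} 0) limit of the PI model
#' and serves as an analytic oracle for the reaction step of the solver.
#'
#' @param c0 Initial density, cells/mm^3, in `[0, K]` (vectorised).
#' @param kin A [kinetics()] object (only `rho` and `K` are used).
#' @param t_days Elapsed time in days (vectorised).
#' @return Density at `t_days`, same shape as `c0`.
#' @export
logistic_reference <- function(c0, kin, t_days) {
  stopifnot(inherits(kin, "pi_kinetics"), is.numeric(c0), is.numeric(t_days))
  if (any(c0 < 0) || any(c0 > kin$K)) {
    abort("`c0` must lie in [0, K].")
  }
  g <- exp(per_year_to_per_day(kin$rho) * t_days)
  kin$K * c0 * g / (kin$K + c0 * (g - 1))
}
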