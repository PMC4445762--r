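#' Spherically symmetric tumor cell density field
#'
#' A radial density profile \eqn{c(r)} on a grid of radii starting at the
#' tumor center `r = 0`, at one instant of simulation time. Stored as a
#' tibble with columns `r_mm` and `density` plus attributes `K` (carrying
#' capacity) and `t_days` (simulation time), so it pipes straight into dplyr
#' and ggplot2.
#'
#' @param r_mm Strictly increasing radial coordinates (mm); the first entry
#'   must be 0.
#' @param density Cell density at each node (cells/mm^3), in `[0, K]`.
#' @param K Carrying capacity (cells/mm^3).
#' @param t_days Simulation time attached to the snapshot (days).
#' @return A tibble of class `radial_field`.
#' @export
radial_field <- function(r_mm, density, K, t_days = 0) {
  stopifnot(is.numeric(r_mm), is.numeric(density),
            length(r_mm) == length(density), length(r_mm) >= 3)
  if (r_mm[1] != 0) abort("radial grid must start at r = 0.")
  if (any(diff(r_mm) <= 0)) abort("radial grid must be strictly increasing.")
  stopifnot(is.numeric(K), length(K) == 1, K > 0)
  if (any(density < 0)) abort("densities must be non-negative.")
  if (any(density > K * (1 + 1e-12))) {
    abort("densities must not exceed the carrying capacity K.")
  }
  out <- tibble(r_mm = as.numeric(r_mm), density = pmin(as.numeric(density), K))
  structure(out, K = K, t_days = t_days,
            class = c("radial_field", class(out)))
}

field_K <- function(field) attr(field, "K")
field_time <- function(field) attr(field, "t_days")

# rebuild a field with new densities/time, keeping grid and K
field_update <- function(field, density, t_days = field_time(field)) {
  radial_field(field$r_mm, density, K = field_K(field), t_days = t_days)
}

#' @export
print.radial_field <- function(x, ...) {
  cat(sprintf("<radial_field> t = %g days, K = %g cells/mm^3, %d nodes to r_max = %g mm\n",
              field_time(x), field_K(x), nrow(x), max(x$r_mm)))
  NextMethod()
}

# finite-volume geometry of a radial grid: cell faces, face areas, volumes.
# Faces sit midway between nodes; the innermost face is r = 0 and the
# outermost face is the last node, so the cell volumes tile the ball exactly
# and summing V*c gives the total cell number.
fv_geometry <- function(r) {
  n <- length(r)
  faces <- c(0, (r[-n] + r[-1]) / 2, r[n])
  list(
    faces = faces,
    area  = 4 * pi * faces^2,                      # length n + 1
    vol   = 4 * pi / 3 * diff(faces^3),            # length n
    dr    = diff(r)                                # node spacing, length n - 1
  )
}

#' Total cell number of a radial field
#'
#' Volume-weighted integral \eqn{\int_0^{r_{max}} 4\pi r^2 c(r)\,dr},
#' evaluated with the same finite-volume quadrature the solver conserves.
#'
#' @param field A [radial_field()].
#' @return Total number of cells (dimensionless count).
#' @export
total_cells <- function(field) {
  stopifnot(inherits(field, "radial_field"))
  geom <- fv_geometry(field$r_mm)
  sum(geom$vol * field$density)
}

#' Imaging radius of a density profile
#'
#' The equivalent spherical radius at which the density profile crosses a
#' given fraction of the carrying capacity — the model's abstraction of an
#' MRI-visible lesion edge (T1Gd edges correspond to a high threshold, T2
#' edges to a low one). Returns the *outermost* crossing, linearly
#' interpolated between grid nodes; profiles that stay below the threshold
#' everywhere give 0.
#'
#' @param field A [radial_field()].
#' @param threshold_fraction Density threshold as a fraction of `K`, in (0, 1).
#' @return Radius in mm.
#' @examples
#' f <- radial_field(seq(0, 40, 0.5), 1e5 * exp(-seq(0, 40, 0.5) / 2), K = 1e5)
#' extract_radius(f, exp(-1)) # ~2 mm
#' @export
extract_radius <- function(field, threshold_fraction) {
  stopifnot(inherits(field, "radial_field"),
            is.numeric(threshold_fraction), length(threshold_fraction) == 1,
            threshold_fraction > 0, threshold_fraction < 1)
  u <- field$density / field_K(field)
  r <- field$r_mm
  thr <- threshold_fraction
  above <- u >= thr
  if (!any(above)) return(0)
  i <- max(which(above))            # outermost node still at/above threshold
  if (i == length(r)) return(r[i])  # profile still above threshold at r_max
  # linear interpolation on the outermost downward crossing
  r[i] + (u[i] - thr) / (u[i] - u[i + 1]) * (r[i + 1] - r[i])
}

# ---- canonical traveling-wave profile --------------------------------------

# Dimensionless critical Fisher-KPP front U(xi): U'' + 2 U' + U(1-U) = 0 with
# U(-inf) = 1, U(+inf) = 0, integrated once per session along the unstable
# manifold of U = 1 and cached. xi is measured in units of the gradient
# length sqrt(D/rho).
canonical_front <- function() {
  if (!is.null(the$front)) return(the$front)
  m <- -1 + sqrt(2)                      # unstable exponent at U = 1
  deriv <- function(x, y, parms) list(c(y[2], -2 * y[2] - y[1] * (1 - y[1])))
  delta <- 1e-7
  xs <- seq(0, 80, by = 0.005)
  sol <- deSolve::ode(c(1 - delta, -delta * m), xs, deriv, NULL,
                      rtol = 1e-10, atol = 1e-13)
  U <- pmin(pmax(sol[, 2], 0), 1)
  keep <- U > 1e-12 & !duplicated(U)
  xi <- sol[keep, 1]
  U <- U[keep]
  # anchor xi = 0 at the U = 1/2 level for a reproducible parametrization
  # (U decreases with xi, so interpolate on the reversed vectors)
  xi <- xi - approx(rev(U), rev(xi), xout = 0.5)$y
  the$front <- list(xi = xi, U = U, m = m, delta = delta)
  the$front
}

# xi coordinate (gradient-length units) where the canonical front passes a
# density level; monotone decreasing U makes this well defined.
front_xi <- function(level) {
  stopifnot(all(level > 0), all(level < 1))
  fr <- canonical_front()
  out <- approx(rev(fr$U), rev(fr$xi), xout = level)$y
  # levels above the integrated range sit on the analytic U = 1 - delta*e^{m xi} tail
  hi <- is.na(out) & level > max(fr$U)
  if (any(hi)) out[hi] <- log((1 - level[hi]) / fr$delta) / fr$m + min(fr$xi) -
      log((1 - max(fr$U)) / fr$delta) / fr$m
  out
}

#' Width of the model's invading front between two density thresholds
#'
#' Distance, in units of the gradient length \eqn{\sqrt{D/\rho}}, between the
#' radii where the steady traveling-wave profile of the PI model crosses two
#' density fractions of `K`. Used to convert a measured T2--T1 imaging radius
#' difference into a gradient length. For the default imaging thresholds
#' (0.80, 0.16) the width is 6.106: the pulled Fisher-KPP front is several
#' times wider between those levels than its asymptotic exponential tail
#' would suggest.
#'
#' @param f_hi Upper density fraction (inner edge, e.g. 0.80 for T1Gd).
#' @param f_lo Lower density fraction (outer edge, e.g. 0.16 for T2).
#' @return Dimensionless width (gradient lengths).
#' @export
front_width <- function(f_hi = 0.80, f_lo = 0.16) {
  stopifnot(f_hi > f_lo, f_lo > 0, f_hi < 1)
  front_xi(f_lo) - front_xi(f_hi)
}

# evaluate the canonical front at arbitrary xi (1 to the left, 0 far right)
front_value <- function(xi) {
  fr <- canonical_front()
  out <- approx(fr$xi, fr$U, xout = xi)$y
  out[xi < min(fr$xi)] <- 1
  out[xi > max(fr$xi)] <- 0
  pmin(pmax(out, 0), 1)
}

#' Construct a near-steady tumor profile with a prescribed imaging radius
#'
#' Builds a radial density field shaped like the PI model's steady traveling
#' front, positioned so that the profile crosses `threshold_fraction * K` at
#' `radius_mm`. Useful as an initial condition that skips the early transient:
#' a simulation started from it immediately grows as a traveling wave.
#'
#' @param kin A [kinetics()] object.
#' @param radius_mm Target imaging radius (mm).
#' @param settings A [solver_settings()] supplying the grid (`dr`, `r_max`).
#' @param threshold_fraction Density fraction defining the imaging radius
#'   (default 0.80, the T1Gd convention).
#' @param t_days Time stamp for the snapshot.
#' @return A [radial_field()].
#' @export
front_profile_field <- function(kin, radius_mm, settings,
                                threshold_fraction = 0.80, t_days = 0) {
  stopifnot(inherits(kin, "pi_kinetics"), radius_mm >= 0,
            radius_mm < settings$r_max)
  r <- grid_from_settings(settings)
  lam <- gradient_length(kin)
  # place the front so U((r - shift)/lambda) = threshold at radius_mm
  shift <- radius_mm - lam * front_xi(threshold_fraction)
  radial_field(r, kin$K * front_value((r - shift) / lam), K = kin$K,
               t_days = t_days)
}

#' Gaussian seed profile
#'
#' A localized Gaussian bolus \eqn{c(r) = A e^{-(r/w)^2}}, the package's
#' generic "small early lesion" initial condition.
#'
#' @inheritParams front_profile_field
#' @param width_mm e-folding width of the bolus (mm).
#' @param amplitude Peak density (defaults to `K`).
#' @return A [radial_field()].
#' @export
gaussian_bolus <- function(kin, settings, width_mm = 2, amplitude = kin$K,
                           t_days = 0) {
  stopifnot(inherits(kin, "pi_kinetics"), width_mm > 0,
            amplitude > 0, amplitude <= kin$K)
  r <- grid_from_settings(settings)
  radial_field(r, amplitude * exp(-(r / width_mm)^2), K = kin$K,
               t_days = t_days)
}
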