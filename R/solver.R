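#' Numerical settings for the radial PI solver
#'
#' @param dr Spatial step (mm).
#' @param dt Time step (days).
#' @param r_max Domain extent (mm). Must comfortably exceed the largest
#'   radius of interest; the outer boundary is zero-flux, so a front reaching
#'   it is contaminated.
#' @param scheme `"semi_implicit"` (default): diffusion advanced by backward
#'   Euler on a conservative finite-volume stencil, proliferation by the
#'   exact logistic map, composed by Strang splitting — unconditionally
#'   stable, positivity preserving and mass conserving for `rho = 0`.
#'   `"explicit"`: forward-Euler diffusion, subject to the stability bound
#'   `dt <= dr^2 / (2 D)` (D in mm^2/day), checked before stepping.
#' @return A list of class `solver_settings`.
#' @export
solver_settings <- function(dr = 0.25, dt = 0.5, r_max = 100,
                            scheme = c("semi_implicit", "explicit")) {
  scheme <- arg_match(scheme)
  stopifnot(dr > 0, dt > 0, r_max > 2 * dr)
  structure(list(dr = dr, dt = dt, r_max = r_max, scheme = scheme),
            class = "solver_settings")
}

grid_from_settings <- function(settings) {
  stopifnot(inherits(settings, "solver_settings"))
  seq(0, settings$r_max, by = settings$dr)
}

# Conservative finite-volume diffusion operator on the sphere. Cell i owns
# the shell between faces; the flux through face i+1/2 is
# A_{i+1/2} * D * (c_{i+1} - c_i)/dr. Zero-flux closures at r = 0 (face area
# 0, which also regularizes the origin of the spherical Laplacian) and at
# r_max. Returns the (symmetric) stiffness matrix L such that
# d(V c)/dt = -L c for pure diffusion.
diffusion_matrix <- function(geom, D_day) {
  n <- length(geom$vol)
  # conductance of interior faces 2..n (face j couples cells j-1 and j)
  g <- D_day * geom$area[2:n] / geom$dr
  Matrix::sparseMatrix(
    i = c(1:n, 1:(n - 1), 2:n),
    j = c(1:n, 2:n, 1:(n - 1)),
    x = c(c(g, 0) + c(0, g), -g, -g),
    symmetric = FALSE
  )
}

# returns function(dens, dt) advancing diffusion one step; factorizations
# cached per dt (the backward-Euler matrix depends on dt).
make_diffusion_stepper <- function(geom, D_day, scheme) {
  n <- length(geom$vol)
  L <- diffusion_matrix(geom, D_day)
  if (scheme == "explicit") {
    Vinv <- 1 / geom$vol
    return(function(dens, dt) dens - dt * Vinv * as.numeric(L %*% dens))
  }
  M <- Matrix::Diagonal(n, geom$vol)
  cache <- new.env(parent = emptyenv())
  function(dens, dt) {
    key <- sprintf("%.15g", dt)
    f <- cache[[key]]
    if (is.null(f)) {
      A <- methods::as(M / dt + L, "symmetricMatrix")
      f <- Matrix::Cholesky(A, LDL = FALSE)
      cache[[key]] <- f
    }
    as.numeric(Matrix::solve(f, geom$vol * dens / dt))
  }
}

# exact logistic map for the reaction term
logistic_step <- function(dens, rho_day, K, dt) {
  if (rho_day == 0) return(dens)
  g <- exp(rho_day * dt)
  K * dens * g / (K + dens * (g - 1))
}

check_bounds <- function(dens, K, t) {
  tol <- 1e-8 * K
  if (min(dens) < -tol || max(dens) > K + tol) {
    abort(sprintf(
      "density left [0, K] at t = %g days (min %.3g, max %.3g): numerical instability; refine dt/dr.",
      t, min(dens), max(dens)))
  }
  pmin(pmax(dens, 0), K) # snap roundoff-scale excursions only (guarded above)
}

#' Simulate PI model growth in spherical symmetry
#'
#' Advances the Proliferation-Invasion reaction-diffusion equation
#' \eqn{\partial c/\partial t = (1/r^2)\,\partial_r (r^2 D\, \partial_r c) +
#' \rho c (1 - c/K)} on a radial grid with zero-flux boundaries at the origin
#' and at `r_max`, returning density snapshots at requested times. Discrete
#' therapy events (radiation fractions, resection) can be interleaved with
#' growth through the `events` argument; the event engine is what the
#' radiation-therapy and resection front ends build on.
#'
#' @param kin A [kinetics()] object (public units: mm^2/year, 1/year).
#' @param initial A [radial_field()] initial condition; its grid defines the
#'   spatial discretization (its spacing should match `settings$dr`).
#' @param duration_days Length of the simulation (days).
#' @param settings A [solver_settings()].
#' @param save_times Times (days, relative to the initial field's time stamp)
#'   at which snapshots are kept. Defaults to ~41 evenly spaced times
#'   including both endpoints. Times are hit exactly by splitting steps.
#' @param events Optional list of events, each `list(t_days =, apply =
#'   function(field) field)`, applied in time order when the simulation
#'   clock reaches `t_days`.
#' @return An object of class `pi_sim`: list with `snapshots` (list of
#'   [radial_field()]), `kinetics`, `settings`. Use [as_tibble()] for a long
#'   tibble, [radius_trajectory()] for imaging radii over time.
#' @examples
#' k <- kinetics(D = 25, rho = 16)
#' s <- solver_settings(dr = 0.5, dt = 1, r_max = 60)
#' sim <- pi_simulate(k, gaussian_bolus(k, s), duration_days = 365, settings = s)
#' radius_trajectory(sim)
#' @export
pi_simulate <- function(kin, initial, duration_days, settings = solver_settings(),
                        save_times = NULL, events = NULL) {
  stopifnot(inherits(kin, "pi_kinetics"), inherits(initial, "radial_field"),
            inherits(settings, "solver_settings"),
            is.numeric(duration_days), duration_days > 0)
  if (abs(field_K(initial) - kin$K) > 1e-9 * kin$K) {
    abort("initial field and kinetics disagree on the carrying capacity K.")
  }
  if (max(initial$density) > kin$K * (1 + 1e-12)) {
    abort("initial density exceeds the carrying capacity K.")
  }
  D_day <- per_year_to_per_day(kin$D)
  rho_day <- per_year_to_per_day(kin$rho)
  r <- initial$r_mm
  geom <- fv_geometry(r)

  if (settings$scheme == "explicit") {
    dt_max <- min(geom$dr)^2 / (2 * D_day)
    if (settings$dt > dt_max) {
      abort(sprintf(
        "explicit scheme unstable: dt = %g days exceeds dr^2/(2D) = %g days.",
        settings$dt, dt_max))
    }
  }

  t0 <- field_time(initial)
  t_end <- t0 + duration_days
  if (is.null(save_times)) {
    save_times <- seq(t0, t_end, length.out = min(41, max(2, ceiling(duration_days / settings$dt) + 1)))
  } else {
    save_times <- t0 + save_times[save_times >= 0 & save_times <= duration_days + 1e-9]
    save_times <- sort(unique(c(save_times)))
  }

  ev_times <- numeric(0)
  if (!is.null(events) && length(events)) {
    ev_times <- map_dbl(events, "t_days")
    if (any(ev_times < t0 - 1e-9)) abort("event scheduled before the initial time.")
    if (is.unsorted(ev_times)) {
      o <- order(ev_times)
      events <- events[o]
      ev_times <- ev_times[o]
    }
  }

  # step boundaries: regular dt grid plus exact save/event times
  bounds <- sort(unique(c(seq(t0, t_end, by = settings$dt), t_end,
                          save_times, ev_times[ev_times <= t_end + 1e-9])))
  bounds <- bounds[bounds <= t_end + 1e-9]

  diffuse <- make_diffusion_stepper(geom, D_day, settings$scheme)
  dens <- initial$density
  snapshots <- list()
  save_set <- save_times
  maybe_save <- function(t, dens) {
    if (length(save_set) && any(abs(save_set - t) < 1e-9)) {
      snapshots[[length(snapshots) + 1]] <<-
        radial_field(r, dens, K = kin$K, t_days = t)
      save_set <<- save_set[abs(save_set - t) >= 1e-9]
    }
  }
  fire_events <- function(t, dens) {
    while (length(events) && events[[1]]$t_days <= t + 1e-9) {
      f <- events[[1]]$apply(radial_field(r, dens, K = kin$K, t_days = t))
      stopifnot(inherits(f, "radial_field"))
      dens <- f$density
      events <<- events[-1]
    }
    dens
  }

  dens <- fire_events(t0, dens)
  maybe_save(t0, dens)
  for (i in seq_len(length(bounds) - 1)) {
    dt <- bounds[i + 1] - bounds[i]
    if (dt < 1e-12) next
    # Strang splitting: half reaction, full diffusion, half reaction
    dens <- logistic_step(dens, rho_day, kin$K, dt / 2)
    dens <- diffuse(dens, dt)
    dens <- logistic_step(dens, rho_day, kin$K, dt / 2)
    dens <- check_bounds(dens, kin$K, bounds[i + 1])
    dens <- fire_events(bounds[i + 1], dens)
    maybe_save(bounds[i + 1], dens)
  }

  structure(list(snapshots = snapshots, kinetics = kin, settings = settings),
            class = "pi_sim")
}

#' @export
print.pi_sim <- function(x, ...) {
  ts <- map_dbl(x$snapshots, field_time)
  cat(sprintf("<pi_sim> %d snapshots over t = [%g, %g] days; D = %g mm^2/yr, rho = %g /yr\n",
              length(x$snapshots), min(ts), max(ts), x$kinetics$D, x$kinetics$rho))
  invisible(x)
}

#' @export
as_tibble.pi_sim <- function(x, ...) {
  list_rbind(map(x$snapshots, function(f) {
    tibble(t_days = field_time(f), r_mm = f$r_mm, density = f$density)
  }))
}

#' Imaging radius over time from a simulation
#'
#' Applies [extract_radius()] to every stored snapshot.
#'
#' @param sim A [pi_simulate()] result.
#' @param threshold_fraction Density fraction of `K` defining the lesion
#'   edge (default 0.80, T1Gd convention; use 0.16 for T2).
#' @return A tibble with columns `t_days`, `radius_mm`.
#' @export
radius_trajectory <- function(sim, threshold_fraction = 0.80) {
  stopifnot(inherits(sim, "pi_sim"))
  tibble(
    t_days = map_dbl(sim$snapshots, field_time),
    radius_mm = map_dbl(sim$snapshots, extract_radius,
                        threshold_fraction = threshold_fraction)
  )
}

# Radius-versus-time curve of an *established* front, re-timed so the first
# threshold's radius crosses `radius_mm` at t = 0. The front starts behind
# the target radius and relaxes onto the discrete traveling wave during a
# pre-roll, which removes the slow initial transient of a freshly
# constructed profile. Returns a tibble with `t_days` (may start < 0) and
# one radius column per (named) threshold; the curve is extended linearly at
# the asymptotic velocity if the simulated window ends before `horizon_days`.
relaxed_radius_curve <- function(kin, radius_mm, horizon_days, settings,
                                 threshold_fraction = 0.80, relax_days = 120,
                                 thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- c(radius_mm = threshold_fraction)
  v_day <- per_year_to_per_day(front_velocity(kin))
  r_back <- max(min(2, radius_mm / 2), radius_mm - v_day * relax_days)
  lead <- (radius_mm - r_back) / v_day
  duration <- lead * 1.3 + horizon_days + 20
  # keep the outermost (lowest-threshold) edge clear of the boundary
  tail_mm <- if (min(thresholds) < thresholds[[1]]) {
    gradient_length(kin) * front_width(thresholds[[1]], min(thresholds))
  } else 0
  head_mm <- 0.93 * settings$r_max - radius_mm - tail_mm
  duration <- min(duration, lead + max(head_mm, 0) / v_day)
  init <- front_profile_field(kin, r_back, settings,
                              threshold_fraction = thresholds[1])
  sim <- pi_simulate(kin, init, duration_days = max(duration, 2 * settings$dt),
                     settings = settings,
                     save_times = seq(0, duration, by = 2 * settings$dt))
  out <- tibble(t_days = map_dbl(sim$snapshots, field_time))
  for (nm in names(thresholds)) {
    out[[nm]] <- map_dbl(sim$snapshots, extract_radius,
                         threshold_fraction = thresholds[[nm]])
  }
  lead_col <- out[[names(thresholds)[1]]]
  if (max(lead_col) < radius_mm) {
    abort("front never reached the anchor radius; enlarge r_max or relax_days.")
  }
  t_c <- approx(lead_col, out$t_days, xout = radius_mm, ties = min)$y
  out$t_days <- out$t_days - t_c
  # linear extension at the asymptotic speed if the window fell short
  if (max(out$t_days) < horizon_days) {
    t_ext <- seq(max(out$t_days) + 2 * settings$dt, horizon_days + 2 * settings$dt,
                 by = 2 * settings$dt)
    ext <- tibble(t_days = t_ext)
    for (nm in names(thresholds)) {
      ext[[nm]] <- out[[nm]][nrow(out)] + v_day * (t_ext - max(out$t_days))
    }
    out <- bind_rows(out, ext)
  }
  names(out)[2] <- if (length(thresholds) == 1) "radius_mm" else names(out)[2]
  out
}

#' Front propagation speed from a simulation or radius series
#'
#' Least-squares slope of imaging radius versus time over a late fitting
#' window, in mm/year. For a converged PI front this estimates the
#' traveling-wave speed \eqn{2\sqrt{D\rho}}. When given a `pi_sim`, the fit
#' refuses to use snapshots whose front is within 5% of the domain boundary
#' (zero-flux contamination).
#'
#' @param x A `pi_sim` object, or a data frame with columns `t_days` and
#'   `radius_mm`.
#' @param threshold_fraction Lesion-edge threshold used when `x` is a
#'   simulation.
#' @param fit_fraction Fraction of the time span, counted from the end, used
#'   for the fit (default: last third, past the pulled-front transient).
#' @return Speed in mm/year.
#' @export
wavefront_speed <- function(x, threshold_fraction = 0.80, fit_fraction = 1 / 3) {
  if (inherits(x, "pi_sim")) {
    traj <- radius_trajectory(x, threshold_fraction)
    r_lim <- 0.95 * max(x$snapshots[[1]]$r_mm)
  } else {
    stopifnot(is.data.frame(x), all(c("t_days", "radius_mm") %in% names(x)))
    traj <- x
    r_lim <- Inf
  }
  if (nrow(traj) < 3) abort("need at least 3 radius observations.")
  t1 <- max(traj$t_days) - fit_fraction * diff(range(traj$t_days))
  win <- traj[traj$t_days >= t1 - 1e-9, ]
  if (nrow(win) < 2) abort("fit window contains fewer than 2 snapshots.")
  if (any(win$radius_mm > r_lim)) {
    abort("front reached the outer boundary inside the fit window; enlarge r_max.")
  }
  per_day_to_per_year(unname(coef(lm(radius_mm ~ t_days, data = win))[2]))
}

#' Plot density profiles of a simulation
#'
#' @param object A `pi_sim` object.
#' @param ... Unused.
#' @return A ggplot: density (fraction of K) versus radius, colored by time.
#' @export
autoplot.pi_sim <- function(object, ...) {
  dat <- as_tibble(object)
  dat$density <- dat$density / object$kinetics$K
  ggplot2::ggplot(dat, ggplot2::aes(.data$r_mm, .data$density,
                                    color = .data$t_days, group = .data$t_days)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "radius (mm)", y = "cell density (fraction of K)",
                  color = "time (days)") +
    ggplot2::theme_minimal()
}
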