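#' Surgical resection of a density field
#'
#' Models resection as removal of all cells inside the resection margin
#' (optionally down to a residual fraction, for sensitivity analyses), with
#' the invisible infiltrative tail beyond the margin untouched — the reason
#' "gross total" resection of a diffuse glioma is never total.
#'
#' @param field A [radial_field()].
#' @param margin_mm Resection margin radius (mm), < domain extent. 0 (a
#'   biopsy) leaves the field unchanged.
#' @param residual_fraction Fraction of density left behind inside the
#'   margin (default 0 = complete removal within the cavity).
#' @return The post-resection [radial_field()], with attributes
#'   `removed_cells` (count) and `removed_fraction` (of total).
#' @examples
#' k <- kinetics(D = 25, rho = 16)
#' s <- solver_settings(r_max = 60)
#' f <- front_profile_field(k, 15, s)
#' post <- apply_resection(f, margin_mm = 15)
#' attr(post, "removed_fraction")
#' @export
apply_resection <- function(field, margin_mm, residual_fraction = 0) {
  stopifnot(inherits(field, "radial_field"),
            is.numeric(margin_mm), length(margin_mm) == 1, margin_mm >= 0,
            residual_fraction >= 0, residual_fraction < 1)
  if (margin_mm >= max(field$r_mm)) {
    abort("resection margin must lie inside the simulation domain.")
  }
  before <- total_cells(field)
  dens <- field$density
  inside <- margin_mm > 0 & field$r_mm <= margin_mm
  dens[inside] <- dens[inside] * residual_fraction
  out <- field_update(field, dens)
  removed <- before - total_cells(out)
  attr(out, "removed_cells") <- removed
  attr(out, "removed_fraction") <- if (before > 0) removed / before else 0
  out
}

#' Resolve a resection extent to a margin radius
#'
#' * `"GTR"` (gross total resection): margin at the visible lesion edge —
#'   the imaging radius at `threshold_fraction` (T1Gd by default).
#' * `"STR"` (subtotal): a configurable fraction of the GTR margin
#'   (default 0.75).
#' * `"biopsy"`: margin 0, nothing removed.
#'
#' @param field The [radial_field()] at the time of surgery.
#' @param extent `"GTR"`, `"STR"` or `"biopsy"`.
#' @param threshold_fraction Imaging threshold defining the visible edge.
#' @param str_fraction STR margin as a fraction of the GTR margin.
#' @return Margin radius in mm.
#' @export
resection_margin <- function(field, extent = c("GTR", "STR", "biopsy"),
                             threshold_fraction = 0.80, str_fraction = 0.75) {
  extent <- arg_match(extent)
  stopifnot(str_fraction > 0, str_fraction < 1)
  gtr <- extract_radius(field, threshold_fraction)
  switch(extent, GTR = gtr, STR = str_fraction * gtr, biopsy = 0)
}

#' Margin needed to remove a given fraction of all tumor cells
#'
#' The smallest radius enclosing `fraction` of the field's volume-integrated
#' cell count, resolved sub-grid by assuming uniform density within each
#' finite-volume cell (exact for piecewise-constant profiles). With
#' `fraction = 0.99` this is the "99% removal margin": how far past the
#' visible edge surgery would need to go to remove 99% of tumor cells —
#' far for diffuse (low rho/D) tumors, close for nodular (high rho/D) ones.
#'
#' @param field A [radial_field()] with positive total mass.
#' @param fraction Target removed fraction, in (0, 1).
#' @return Radius in mm.
#' @examples
#' f <- radial_field(seq(0, 20, 0.1), rep(c(1e5, 0), c(101, 100)), K = 1e5)
#' margin_for_fraction_removed(f, 0.99) # ~ 0.99^(1/3) * 10
#' @export
margin_for_fraction_removed <- function(field, fraction = 0.99) {
  stopifnot(inherits(field, "radial_field"),
            is.numeric(fraction), length(fraction) == 1,
            fraction > 0, fraction < 1)
  geom <- fv_geometry(field$r_mm)
  mass <- geom$vol * field$density
  total <- sum(mass)
  if (total <= 0) abort("field has no tumor cells.")
  target <- fraction * total
  cum <- cumsum(mass)
  i <- which(cum >= target - 1e-12 * total)[1]
  m_lo <- if (i > 1) cum[i - 1] else 0
  r_lo <- geom$faces[i]
  dens <- field$density[i]
  if (dens <= 0) return(r_lo)
  # invert M(R) = m_lo + (4/3) pi dens (R^3 - r_lo^3) within the cell
  (r_lo^3 + (target - m_lo) * 3 / (4 * pi * dens))^(1 / 3)
}

#' Time for the lesion to reach a fatal size
#'
#' Converts a (possibly treated) growth simulation into a survival
#' surrogate: the first time the imaging radius reaches a uniform fatal
#' radius. Patients whose tumor never reaches it within the horizon are
#' censored — the standard device for turning patient-specific simulations
#' into survival curves.
#'
#' @param kin A [kinetics()] object.
#' @param initial Initial [radial_field()].
#' @param fatal_radius_mm Uniform fatal T1Gd-equivalent radius (mm; default
#'   35, configurable). Must be < `r_max`.
#' @param plan Optional [radiation_plan()] applied during growth.
#' @param resection Optional list `list(t_days =, extent =)` (or
#'   `margin_mm` instead of `extent`) describing one surgery.
#' @param horizon_days Censoring horizon.
#' @param settings [solver_settings()].
#' @param threshold_fraction Imaging threshold of the tracked radius.
#' @return One-row tibble of class `survival_surrogate`: `time_to_fatal_days`,
#'   `censored`, `fatal_radius_mm`, `already_fatal`.
#' @export
time_to_fatal_radius <- function(kin, initial, fatal_radius_mm = 35,
                                 plan = NULL, resection = NULL,
                                 horizon_days = 5 * DAYS_PER_YEAR,
                                 settings = solver_settings(),
                                 threshold_fraction = 0.80) {
  stopifnot(inherits(kin, "pi_kinetics"), inherits(initial, "radial_field"),
            fatal_radius_mm > 0)
  if (fatal_radius_mm >= max(initial$r_mm)) {
    abort("fatal radius must lie inside the simulation domain.")
  }
  r0 <- extract_radius(initial, threshold_fraction)
  if (r0 >= fatal_radius_mm) {
    return(surrogate_row(0, FALSE, fatal_radius_mm, already_fatal = TRUE))
  }
  events <- list()
  if (!is.null(resection)) {
    events <- c(events, list(list(
      t_days = resection$t_days %||% field_time(initial),
      apply = function(field) {
        margin <- resection$margin_mm %||%
          resection_margin(field, resection$extent %||% "GTR",
                           threshold_fraction = threshold_fraction,
                           str_fraction = resection$str_fraction %||% 0.75)
        apply_resection(field, margin,
                        residual_fraction = resection$residual_fraction %||% 0)
      })))
  }
  if (!is.null(plan) && nrow(plan$fractions)) {
    events <- c(events, map(seq_len(nrow(plan$fractions)), function(i) {
      list(t_days = plan$fractions$t_days[i],
           apply = function(field) apply_fraction(field, plan, i))
    }))
  }
  n_save <- max(61, min(301, ceiling(horizon_days / (2 * settings$dt))))
  sim <- pi_simulate(kin, initial, duration_days = horizon_days,
                     settings = settings,
                     save_times = seq(0, horizon_days, length.out = n_save),
                     events = if (length(events)) events else NULL)
  traj <- radius_trajectory(sim, threshold_fraction)
  hit <- which(traj$radius_mm >= fatal_radius_mm)
  if (!length(hit)) {
    return(surrogate_row(horizon_days, TRUE, fatal_radius_mm))
  }
  i <- hit[1]
  t_hit <- if (i == 1) traj$t_days[1] else {
    approx(traj$radius_mm[(i - 1):i], traj$t_days[(i - 1):i],
           xout = fatal_radius_mm, ties = min)$y
  }
  surrogate_row(t_hit - field_time(initial), FALSE, fatal_radius_mm)
}

surrogate_row <- function(time, censored, fatal, already_fatal = FALSE) {
  out <- tibble(time_to_fatal_days = time, censored = censored,
                fatal_radius_mm = fatal, already_fatal = already_fatal)
  structure(out, class = c("survival_surrogate", class(out)))
}
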