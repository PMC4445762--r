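#' Build an untreated virtual control (UVC)
#'
#' The UVC is the PI model's prediction of how a patient's tumor would have
#' grown with no therapy: a radius-versus-time curve anchored to a
#' pre-treatment observation, against which treated scans are compared.
#'
#' Two construction modes:
#' * `"simulated"` (default): runs the radial PI solver from a front placed
#'   behind the anchor, lets it relax onto the discrete traveling wave for
#'   `relax_days`, and time-shifts the resulting radius curve so it passes
#'   through the anchor exactly. The pre-roll removes the slow pulled-front
#'   transient a freshly constructed profile would otherwise carry.
#' * `"linear"`: the traveling-wave asymptote
#'   \eqn{r(t) = r_0 + 2\sqrt{D\rho}\,(t - t_0)}. Cheap, and within a few
#'   percent of the simulated curve for an established front.
#'
#' @param kin A [kinetics()] object for the patient.
#' @param anchor The pre-treatment observation the UVC passes through: a
#'   list or one-row data frame with `t_days` and `radius_mm` (> 0).
#'   Conventionally the last pre-treatment scan.
#' @param horizon_days How far past the anchor to extend the curve.
#' @param mode `"simulated"` or `"linear"`.
#' @param settings [solver_settings()] for simulated mode; `r_max` is
#'   enlarged automatically if the horizon outgrows it.
#' @param threshold_fraction Imaging threshold of the radii (T1Gd default).
#' @param n_points Number of curve points returned.
#' @param relax_days Pre-roll length for simulated mode (days); shortened
#'   automatically when the anchor radius leaves no room to start behind it.
#' @return A tibble of class `pi_uvc` with columns `t_days`, `radius_mm`,
#'   and attributes `kinetics`, `anchor`, `mode`.
#' @examples
#' uvc <- build_uvc(kinetics(D = 25, rho = 16),
#'                  anchor = list(t_days = 0, radius_mm = 20),
#'                  horizon_days = 91.3125, mode = "linear")
#' tail(uvc, 1) # ~30 mm at day 91
#' @export
build_uvc <- function(kin, anchor, horizon_days, mode = c("simulated", "linear"),
                      settings = NULL, threshold_fraction = 0.80,
                      n_points = 81, relax_days = 120) {
  mode <- arg_match(mode)
  stopifnot(inherits(kin, "pi_kinetics"), horizon_days > 0)
  anchor <- as.list(anchor)
  stopifnot(is.numeric(anchor$t_days), is.numeric(anchor$radius_mm),
            anchor$radius_mm > 0)
  v_day <- per_year_to_per_day(front_velocity(kin))
  if (mode == "linear") {
    times <- seq(anchor$t_days, anchor$t_days + horizon_days,
                 length.out = n_points)
    radii <- anchor$radius_mm + v_day * (times - anchor$t_days)
  } else {
    if (is.null(settings)) {
      r_need <- anchor$radius_mm + v_day * horizon_days * 1.3 +
        10 * gradient_length(kin) + 10
      settings <- solver_settings(dr = 0.25, dt = 0.5, r_max = r_need)
    }
    if (anchor$radius_mm >= settings$r_max) {
      abort("anchor radius exceeds the simulation domain r_max.")
    }
    traj <- relaxed_radius_curve(kin, anchor$radius_mm, horizon_days, settings,
                                 threshold_fraction = threshold_fraction,
                                 relax_days = relax_days)
    times <- seq(anchor$t_days, anchor$t_days + horizon_days,
                 length.out = n_points)
    radii <- approx(traj$t_days + anchor$t_days, traj$radius_mm,
                    xout = times, ties = min)$y
    radii <- cummax(radii) # guard roundoff-scale dips; growth is monotone
  }
  out <- tibble(t_days = times, radius_mm = radii)
  structure(out, kinetics = kin, anchor = anchor, mode = mode,
            threshold_fraction = threshold_fraction,
            class = c("pi_uvc", class(out)))
}

#' @export
print.pi_uvc <- function(x, ...) {
  a <- attr(x, "anchor")
  cat(sprintf("<pi_uvc> %s mode, anchored at t = %g d, r = %g mm; horizon %g d\n",
              attr(x, "mode"), a$t_days, a$radius_mm, max(x$t_days) - a$t_days))
  NextMethod()
}

#' Days Gained treatment-response score
#'
#' Compares a post-treatment lesion radius with the patient's untreated
#' virtual control: the score is the horizontal (time-axis) distance from
#' the UVC curve to the post-treatment point,
#' \deqn{DG = t_{post} - t^*,\qquad r_{UVC}(t^*) = r_{post},}
#' i.e. the number of days of untreated growth that therapy deflected. A
#' post-treatment radius equal to the UVC prediction scores 0; radii below
#' the anchor saturate at the elapsed time (flagged); radii above the UVC
#' curve give negative scores (growth faster than the untreated prediction).
#'
#' @param uvc A [build_uvc()] trajectory.
#' @param post_t_days Acquisition time of the post-treatment scan (days,
#'   same clock as the UVC; must lie within the UVC horizon).
#' @param post_radius_mm Post-treatment equivalent spherical radius (mm).
#' @return A one-row tibble of class `days_gained_score`: `dg_days`,
#'   `t_star_days`, `post_t_days`, `post_radius_mm`, `saturated`.
#' @examples
#' uvc <- build_uvc(kinetics(D = 25, rho = 16),
#'                  anchor = list(t_days = 0, radius_mm = 20),
#'                  horizon_days = 180, mode = "linear")
#' days_gained(uvc, post_t_days = 91, post_radius_mm = 25)
#' @export
days_gained <- function(uvc, post_t_days, post_radius_mm) {
  stopifnot(inherits(uvc, "pi_uvc"),
            is.numeric(post_t_days), length(post_t_days) == 1,
            is.numeric(post_radius_mm), length(post_radius_mm) == 1,
            post_radius_mm >= 0)
  anchor <- attr(uvc, "anchor")
  if (post_t_days < anchor$t_days - 1e-9 || post_t_days > max(uvc$t_days) + 1e-9) {
    abort("post-treatment scan time must lie within [anchor time, UVC horizon].")
  }
  r <- uvc$radius_mm
  t <- uvc$t_days
  if (any(diff(r) < -1e-9)) abort("UVC radii are not non-decreasing.")
  saturated <- FALSE
  if (post_radius_mm <= r[1]) {
    t_star <- t[1]
    saturated <- post_radius_mm < r[1]
  } else if (post_radius_mm > r[length(r)]) {
    # beyond the stored horizon: extrapolate with the terminal slope
    n <- length(r)
    slope <- (r[n] - r[n - 1]) / (t[n] - t[n - 1])
    t_star <- t[n] + (post_radius_mm - r[n]) / slope
  } else {
    # earliest crossing: on flat segments take the left end
    t_star <- approx(r, t, xout = post_radius_mm, ties = min)$y
  }
  out <- tibble(
    dg_days = post_t_days - t_star,
    t_star_days = t_star,
    post_t_days = post_t_days,
    post_radius_mm = post_radius_mm,
    saturated = saturated
  )
  structure(out, uvc = uvc, class = c("days_gained_score", class(out)))
}

#' Classify a Days Gained score as responder / non-responder
#'
#' A score at or above the cutoff is a responder (`>=` convention: a patient
#' exactly at the cutoff counts as responding). The cutoff is a required,
#' explicit input: no clinically validated default exists, and silently
#' encoding one would be worse than asking.
#'
#' @param score A [days_gained()] result, or a numeric vector of scores.
#' @param cutoff_days Non-negative responder cutoff (days).
#' @return Character vector, `"responder"` or `"non-responder"`.
#' @export
classify_response <- function(score, cutoff_days) {
  stopifnot(is.numeric(cutoff_days), length(cutoff_days) == 1, cutoff_days >= 0)
  dg <- if (inherits(score, "days_gained_score")) score$dg_days else score
  stopifnot(is.numeric(dg))
  ifelse(dg >= cutoff_days, "responder", "non-responder")
}

#' Plot a UVC with an optional Days Gained annotation
#'
#' @param object A `pi_uvc` trajectory.
#' @param score Optional [days_gained()] result to annotate.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pi_uvc <- function(object, score = NULL, ...) {
  anchor <- attr(object, "anchor")
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$t_days, .data$radius_mm)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::annotate("point", x = anchor$t_days, y = anchor$radius_mm,
                      shape = 21, fill = "white") +
    ggplot2::labs(x = "time (days)", y = "T1Gd-equivalent radius (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(score)) {
    stopifnot(inherits(score, "days_gained_score"))
    p <- p +
      ggplot2::annotate("segment",
                        x = score$t_star_days, xend = score$post_t_days,
                        y = score$post_radius_mm, yend = score$post_radius_mm,
                        linetype = 2) +
      ggplot2::annotate("point", x = score$post_t_days,
                        y = score$post_radius_mm, color = "firebrick") +
      ggplot2::annotate("text",
                        x = (score$t_star_days + score$post_t_days) / 2,
                        y = score$post_radius_mm,
                        label = sprintf("DG = %.0f d", score$dg_days),
                        vjust = -0.6)
  }
  p
}
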