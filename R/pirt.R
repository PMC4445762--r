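#' Fractionated radiation plan with linear-quadratic response parameters
#'
#' @param fractions Data frame with columns `t_days` (strictly increasing
#'   delivery times) and `dose_Gy` (positive doses per fraction). A zero-row
#'   data frame is a valid "no therapy" plan.
#' @param alpha Radiosensitivity (1/Gy), >= 0. Patient-specific; the
#'   proliferation rate rho is the imaging correlate of radiosensitivity, so
#'   fast-proliferating tumors respond with larger alpha.
#' @param alpha_beta_ratio alpha/beta ratio (Gy), > 0; 10 Gy is the
#'   conventional tumor-tissue value. beta is derived as
#'   `alpha / alpha_beta_ratio`.
#' @return A list of class `radiation_plan` with `fractions`, `alpha`,
#'   `alpha_beta_ratio`, `beta`.
#' @export
radiation_plan <- function(fractions, alpha, alpha_beta_ratio = 10) {
  stopifnot(is.data.frame(fractions),
            all(c("t_days", "dose_Gy") %in% names(fractions)),
            is.numeric(alpha), length(alpha) == 1, alpha >= 0,
            is.numeric(alpha_beta_ratio), alpha_beta_ratio > 0)
  fractions <- as_tibble(fractions)[c("t_days", "dose_Gy")]
  if (nrow(fractions)) {
    if (any(fractions$dose_Gy <= 0)) abort("fraction doses must be positive.")
    if (any(diff(fractions$t_days) <= 0)) {
      abort("fraction times must be strictly increasing.")
    }
  }
  structure(list(fractions = fractions, alpha = alpha,
                 alpha_beta_ratio = alpha_beta_ratio,
                 beta = alpha / alpha_beta_ratio),
            class = "radiation_plan")
}

#' @export
print.radiation_plan <- function(x, ...) {
  cat(sprintf("<radiation_plan> %d fractions, total %g Gy; alpha = %g /Gy, alpha/beta = %g Gy\n",
              nrow(x$fractions), sum(x$fractions$dose_Gy), x$alpha,
              x$alpha_beta_ratio))
  invisible(x)
}

#' Standard-of-care external beam schedule
#'
#' Weekday fractions of `dose_Gy` for `weeks` weeks (default 2 Gy x 5 /week
#' x 6 weeks = 60 Gy), the conventional glioblastoma protocol.
#'
#' @param alpha,alpha_beta_ratio Passed to [radiation_plan()].
#' @param start_day First fraction day.
#' @param dose_Gy Dose per fraction.
#' @param weeks Number of treatment weeks.
#' @param per_week Fractions per week (consecutive days from each week's
#'   start).
#' @return A [radiation_plan()].
#' @examples
#' standard_rt_plan(alpha = 0.34)
#' @export
standard_rt_plan <- function(alpha, alpha_beta_ratio = 10, start_day = 0,
                             dose_Gy = 2, weeks = 6, per_week = 5) {
  days <- as.vector(outer(seq_len(per_week) - 1, 7 * (seq_len(weeks) - 1), "+"))
  radiation_plan(tibble(t_days = start_day + sort(days), dose_Gy = dose_Gy),
                 alpha = alpha, alpha_beta_ratio = alpha_beta_ratio)
}

#' Linear-quadratic surviving fraction
#'
#' Fraction of cells surviving an acute dose `d`:
#' \deqn{S(d) = e^{-\alpha d - \beta d^2},\qquad \beta = \alpha / (\alpha/\beta).}
#'
#' @param alpha Radiosensitivity (1/Gy), >= 0 (vectorised).
#' @param dose_Gy Dose (Gy), >= 0 (vectorised).
#' @param alpha_beta_ratio alpha/beta ratio (Gy).
#' @return Surviving fraction(s) in (0, 1].
#' @examples
#' surviving_fraction(0.340, 2) # exp(-0.816)
#' surviving_fraction(0.016, 2) # exp(-0.0384)
#' @export
surviving_fraction <- function(alpha, dose_Gy, alpha_beta_ratio = 10) {
  stopifnot(is.numeric(alpha), all(alpha >= 0),
            is.numeric(dose_Gy), is.numeric(alpha_beta_ratio),
            all(alpha_beta_ratio > 0))
  if (any(dose_Gy < 0)) abort("dose must be non-negative.")
  beta <- alpha / alpha_beta_ratio
  exp(-alpha * dose_Gy - beta * dose_Gy^2)
}

#' Apply one radiation fraction to a density field
#'
#' Instantaneous, density-modulated cell kill:
#' \deqn{c \to c - (1 - S)\,c\,(1 - c/K),}
#' where `S` is the linear-quadratic surviving fraction of the fraction's
#' dose. The `(1 - c/K)` factor ties radiosensitivity to proliferative
#' activity: cells in saturated, quiescent regions respond less, mirroring
#' the link between proliferation and radiation response that makes rho the
#' imaging correlate of alpha.
#'
#' @param field A [radial_field()].
#' @param plan A [radiation_plan()].
#' @param fraction_index Which fraction of the plan to apply.
#' @return The irradiated [radial_field()].
#' @export
apply_fraction <- function(field, plan, fraction_index) {
  stopifnot(inherits(field, "radial_field"), inherits(plan, "radiation_plan"),
            fraction_index >= 1, fraction_index <= nrow(plan$fractions))
  S <- surviving_fraction(plan$alpha, plan$fractions$dose_Gy[fraction_index],
                          plan$alpha_beta_ratio)
  K <- field_K(field)
  c0 <- field$density
  field_update(field, c0 - (1 - S) * c0 * (1 - c0 / K))
}

#' Simulate PI growth under fractionated radiation (PIRT)
#'
#' Interleaves PI growth with instantaneous [apply_fraction()] events at the
#' plan's delivery times. With an empty plan the computation reduces exactly
#' to [pi_simulate()] (same code path, identical output).
#'
#' @inheritParams pi_simulate
#' @param plan A [radiation_plan()]; fraction times are measured on the same
#'   clock as the initial field and must fall within the simulated window.
#' @return A `pi_sim` object.
#' @examples
#' k <- kinetics(D = 25, rho = 16)
#' s <- solver_settings(dr = 0.5, dt = 1, r_max = 60)
#' sim <- simulate_pirt(k, front_profile_field(k, 12, s),
#'                      standard_rt_plan(alpha = 0.34),
#'                      duration_days = 60, settings = s)
#' @export
simulate_pirt <- function(kin, initial, plan, duration_days,
                          settings = solver_settings(), save_times = NULL) {
  stopifnot(inherits(plan, "radiation_plan"))
  t0 <- field_time(initial)
  events <- NULL
  if (nrow(plan$fractions)) {
    if (any(plan$fractions$t_days < t0 - 1e-9)) {
      abort("radiation fraction scheduled before the simulation start.")
    }
    if (any(plan$fractions$t_days > t0 + duration_days + 1e-9)) {
      abort("radiation fraction scheduled after the simulation end.")
    }
    events <- map(seq_len(nrow(plan$fractions)), function(i) {
      list(t_days = plan$fractions$t_days[i],
           apply = function(field) apply_fraction(field, plan, i))
    })
  }
  pi_simulate(kin, initial, duration_days, settings = settings,
              save_times = save_times, events = events)
}
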