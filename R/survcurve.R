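#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of survival from (possibly right-censored)
#' time-to-event data, computed with the survival package and returned as a
#' tidy step-function table (a row per distinct event/censoring time, plus a
#' `time = 0, survival = 1` origin row).
#'
#' @param times Event or censoring times (days), >= 0.
#' @param event Logical (or 0/1): `TRUE` if the event was observed, `FALSE`
#'   if censored.
#' @return Tibble of class `survival_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @examples
#' kaplan_meier(c(1, 2, 3), c(TRUE, TRUE, TRUE))
#' @export
kaplan_meier <- function(times, event) {
  stopifnot(is.numeric(times), all(times >= 0), length(times) == length(event))
  event <- as.logical(event)
  fit <- survival::survfit(survival::Surv(times, event) ~ 1)
  out <- tibble(
    time = c(0, fit$time),
    n_risk = c(length(times), fit$n.risk),
    n_event = c(0, fit$n.event),
    n_censor = c(0, fit$n.censor),
    survival = c(1, fit$surv)
  )
  structure(out, class = c("survival_curve", class(out)))
}

#' Median of a survival curve
#'
#' First time the Kaplan-Meier estimate drops to 0.5 or below; `NA` if it
#' never does within the observed range.
#'
#' @param curve A [kaplan_meier()] result.
#' @return Time (days) or `NA`.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  i <- which(curve$survival <= 0.5)
  if (!length(i)) NA_real_ else curve$time[i[1]]
}

#' Log-rank test between survival groups (reporting utility)
#'
#' Thin wrapper around `survival::survdiff`.
#'
#' @param times,event As in [kaplan_meier()].
#' @param group Group membership vector.
#' @return One-row tibble: `chisq`, `df`, `p_value`.
#' @export
logrank_test <- function(times, event, group) {
  stopifnot(length(times) == length(group))
  sd <- survival::survdiff(survival::Surv(times, as.logical(event)) ~ group)
  df <- length(sd$n) - 1
  tibble(chisq = sd$chisq, df = df,
         p_value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' @export
autoplot.survival_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$time, .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival fraction") +
    ggplot2::theme_minimal()
}
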