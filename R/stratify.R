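#' Youden-optimal rho/D threshold for a binary label
#'
#' Exhaustively scans candidate thresholds (the midpoints between adjacent
#' sorted unique rho/D values, plus the lowest value itself so degenerate
#' inputs report J = 0) and returns the one maximizing Youden's
#' \eqn{J = sensitivity + specificity - 1}. Ties are broken toward the
#' lower threshold. The class predicted on the low-rho/D side ("positive",
#' e.g. IDH1-mutant, which carries lower rho/D) defaults to the class with
#' the smaller mean, unless forced via `low_label`.
#'
#' @param samples Data frame with columns `rho_over_D` (> 0, 1/mm^2) and
#'   `label` (exactly two distinct values, each present at least once).
#' @param low_label Which label is predicted below the threshold; default:
#'   the label with the lower mean rho/D.
#' @return An object of class `ratio_threshold`: `threshold`, `sensitivity`
#'   (detection rate of `low_label` below threshold), `specificity`,
#'   `youden_j`, `low_label`, `high_label`, and a `scan` tibble with every
#'   candidate. Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(
#'   rho_over_D = c(rlnorm(20, log(0.1), 0.5), rlnorm(20, log(0.5), 0.5)),
#'   label = rep(c("mutant", "wildtype"), each = 20))
#' fit_threshold(d)
#' @export
fit_threshold <- function(samples, low_label = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("rho_over_D", "label") %in% names(samples)))
  x <- samples$rho_over_D
  lab <- as.character(samples$label)
  stopifnot(is.numeric(x), all(x > 0))
  classes <- sort(unique(lab))
  if (length(classes) != 2) {
    abort(sprintf("need exactly 2 label classes, got %d.", length(classes)))
  }
  if (is.null(low_label)) {
    means <- tapply(x, lab, mean)
    low_label <- names(means)[which.min(means)]
  }
  stopifnot(low_label %in% classes)
  high_label <- setdiff(classes, low_label)
  u <- sort(unique(x))
  cand <- c(u[1], if (length(u) > 1) (u[-length(u)] + u[-1]) / 2)
  pos <- lab == low_label
  scan <- tibble(
    threshold = cand,
    sensitivity = map_dbl(cand, ~ mean(x[pos] < .x)),
    specificity = map_dbl(cand, ~ mean(x[!pos] >= .x))
  )
  scan$youden_j <- scan$sensitivity + scan$specificity - 1
  best <- which.max(scan$youden_j) # first max = lowest threshold on ties
  structure(list(
    threshold = scan$threshold[best],
    sensitivity = scan$sensitivity[best],
    specificity = scan$specificity[best],
    youden_j = scan$youden_j[best],
    low_label = low_label, high_label = high_label,
    direction = sprintf("rho/D < threshold predicts '%s'", low_label),
    n = length(x), scan = scan
  ), class = "ratio_threshold")
}

#' @export
print.ratio_threshold <- function(x, ...) {
  cat("<ratio_threshold>\n")
  cat(sprintf("  threshold = %.4g /mm^2  (%s)\n", x$threshold, x$direction))
  cat(sprintf("  sensitivity = %.1f%%  specificity = %.1f%%  Youden J = %.3f  (n = %d)\n",
              100 * x$sensitivity, 100 * x$specificity, x$youden_j, x$n))
  invisible(x)
}

#' @rdname fit_threshold
#' @param x,object A `ratio_threshold` object.
#' @param ... Unused.
#' @export
tidy.ratio_threshold <- function(x, ...) x$scan

#' @rdname fit_threshold
#' @export
glance.ratio_threshold <- function(x, ...) {
  tibble(threshold = x$threshold, sensitivity = x$sensitivity,
         specificity = x$specificity, youden_j = x$youden_j,
         low_label = x$low_label, high_label = x$high_label, n = x$n)
}

#' @rdname fit_threshold
#' @export
autoplot.ratio_threshold <- function(object, ...) {
  ggplot2::ggplot(object$scan, ggplot2::aes(.data$threshold, .data$youden_j)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2,
                        color = "firebrick") +
    ggplot2::labs(x = expression(rho / D ~ threshold ~ (mm^-2)),
                  y = "Youden J") +
    ggplot2::theme_minimal()
}

#' Assign low / moderate / high invasiveness strata
#'
#' Splits rho/D values at two cutpoints with the half-open convention
#' low `< c1 <=` moderate `< c2 <=` high (a value exactly at a cutpoint
#' joins the upper stratum). Low rho/D means diffuse, invasion-dominated
#' disease; high rho/D means nodular, proliferation-dominated disease. With
#' `cutpoints = NULL` the cohort's tertiles are used, which balances the
#' stratum sizes to within one patient for distinct values.
#'
#' @param rho_over_D Numeric vector of aggressiveness ratios (1/mm^2).
#' @param cutpoints Strictly increasing pair `c(c1, c2)`, or `NULL` for
#'   tertile cutpoints.
#' @return Ordered factor with levels `low`, `moderate`, `high`.
#' @examples
#' assign_strata(c(0.1, 0.5, 2), cutpoints = c(0.3, 1))
#' @export
assign_strata <- function(rho_over_D, cutpoints = NULL) {
  stopifnot(is.numeric(rho_over_D), all(rho_over_D > 0))
  if (is.null(cutpoints)) {
    cutpoints <- unname(quantile(rho_over_D, c(1 / 3, 2 / 3)))
  }
  stopifnot(length(cutpoints) == 2, diff(cutpoints) > 0)
  cut(rho_over_D, breaks = c(-Inf, cutpoints, Inf),
      labels = c("low", "moderate", "high"),
      right = FALSE, ordered_result = TRUE)
}

#' Compare rho/D between two labeled groups (reporting utility)
#'
#' Thin wrapper around a Welch two-sample t test on log-transformed rho/D
#' (the ratio is log-normal-like: positive and right-skewed).
#'
#' @inheritParams fit_threshold
#' @param log_scale Test on log(rho/D) (default) or raw values.
#' @return One-row tibble: group means, estimate of the difference,
#'   `statistic`, `p_value`.
#' @export
ratio_group_test <- function(samples, log_scale = TRUE) {
  stopifnot(is.data.frame(samples),
            all(c("rho_over_D", "label") %in% names(samples)))
  y <- if (log_scale) log(samples$rho_over_D) else samples$rho_over_D
  g <- factor(samples$label)
  stopifnot(nlevels(g) == 2)
  tt <- t.test(y ~ g)
  tibble(
    group1 = levels(g)[1], group2 = levels(g)[2],
    mean1 = unname(tt$estimate[1]), mean2 = unname(tt$estimate[2]),
    statistic = unname(tt$statistic), p_value = tt$p.value,
    scale = if (log_scale) "log" else "raw"
  )
}
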