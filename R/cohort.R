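#' Specification of a synthetic virtual-patient cohort
#'
#' Defines the population that the virtual-cohort engine draws from: (D,
#' rho) are sampled independently from log-normal distributions (positive
#' and right-skewed, matching the spread of imaging-calibrated kinetic
#' parameters across real glioblastoma cohorts), serial two-modality scans
#' are synthesized with additive Gaussian radius noise, and a single seed
#' fixes all randomness. The default medians (D = 25 mm^2/yr, rho = 16 /yr,
#' i.e. a median velocity of 40 mm/yr) and spreads are representative
#' placeholders for the published population ranges, not fitted values;
#' every one is configurable.
#'
#' @param n Number of patients (>= 1).
#' @param D_median,D_sdlog Log-normal median (mm^2/yr) and log-sd of D.
#' @param rho_median,rho_sdlog Log-normal median (1/yr) and log-sd of rho.
#' @param K Carrying capacity (cells/mm^3), shared by all patients.
#' @param noise_sd_mm SD of additive radius measurement noise (mm).
#' @param scan_schedule_days Times of the serial scans (days from first).
#' @param initial_radius_mm T1Gd-equivalent radius at the first scan.
#' @param seed Integer seed fixing all randomness of the cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, D_median = 25, D_sdlog = 0.7,
                        rho_median = 16, rho_sdlog = 0.7, K = 1e5,
                        noise_sd_mm = 1,
                        scan_schedule_days = c(0, 90, 180, 270),
                        initial_radius_mm = 10, seed = 1L) {
  stopifnot(n >= 1, D_median > 0, D_sdlog >= 0, rho_median > 0, rho_sdlog >= 0,
            K > 0, noise_sd_mm >= 0, length(scan_schedule_days) >= 1,
            all(diff(scan_schedule_days) > 0), scan_schedule_days[1] >= 0,
            initial_radius_mm > 0, is.numeric(seed))
  structure(list(n = as.integer(n), D_median = D_median, D_sdlog = D_sdlog,
                 rho_median = rho_median, rho_sdlog = rho_sdlog, K = K,
                 noise_sd_mm = noise_sd_mm,
                 scan_schedule_days = scan_schedule_days,
                 initial_radius_mm = initial_radius_mm,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Draw the kinetic parameters of a virtual cohort
#'
#' Reproducible given `spec$seed`: the same spec always yields the same
#' patients.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble: `patient_id`, `D`, `rho`, `K`, `velocity`,
#'   `gradient_length`, `rho_over_D`.
#' @export
sample_patients <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr_seed(spec$seed, {
    D <- rlnorm(spec$n, log(spec$D_median), spec$D_sdlog)
    rho <- rlnorm(spec$n, log(spec$rho_median), spec$rho_sdlog)
  })
  tibble(
    patient_id = sprintf("VP%03d", seq_len(spec$n)),
    D = D, rho = rho, K = spec$K,
    velocity = 2 * sqrt(D * rho),
    gradient_length = sqrt(D / rho),
    rho_over_D = rho / D
  )
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# solver settings sized to a patient and horizon: enough headroom for the
# T2 edge plus the growth expected over the horizon
trial_settings <- function(kin, r_start, horizon_days, dr = 0.25, dt = 1) {
  v_day <- per_year_to_per_day(front_velocity(kin))
  r_max <- r_start + 8 * gradient_length(kin) + 1.2 * v_day * horizon_days + 8
  solver_settings(dr = dr, dt = dt, r_max = r_max)
}

#' Synthesize a serial two-modality observation series for one patient
#'
#' Simulates untreated PI growth from a near-steady front at the spec's
#' initial radius and reads off paired T1Gd (0.80 K) and T2 (0.16 K) radii
#' at the scheduled scan times, then adds Gaussian measurement noise.
#' Draws violating physical constraints (negative radii, or a T2 radius
#' inside the T1Gd radius at the same timepoint) are resampled. With
#' `noise_sd_mm = 0` the returned radii equal the simulated threshold radii
#' exactly.
#'
#' Uses the current RNG state; seed it (or go through
#' [run_virtual_trial()], which seeds everything from the spec) for
#' reproducibility.
#'
#' @param kin A [kinetics()] object for the patient.
#' @param spec A [cohort_spec()] (supplies schedule, noise, thresholds).
#' @param f_t1,f_t2 Imaging density thresholds.
#' @param patient_id Identifier written into the table.
#' @param truth Optional precomputed [simulate_truth_radii()] table; supply
#'   it when drawing many noise replicates of the same patient so the growth
#'   simulation runs once.
#' @return Observation tibble: `patient_id`, `t_days`, `modality`,
#'   `radius_mm`.
#' @export
synthesize_observations <- function(kin, spec, f_t1 = 0.80, f_t2 = 0.16,
                                    patient_id = "VP001", truth = NULL) {
  stopifnot(inherits(kin, "pi_kinetics"), inherits(spec, "cohort_spec"))
  if (is.null(truth)) truth <- simulate_truth_radii(kin, spec, f_t1, f_t2)
  noisy <- pmap(truth, function(t_days, r_t1, r_t2) {
    for (i in 1:1000) {
      o1 <- r_t1 + rnorm(1, 0, spec$noise_sd_mm)
      o2 <- r_t2 + rnorm(1, 0, spec$noise_sd_mm)
      if (o1 >= 0 && o2 >= o1) break
    }
    tibble(t_days = t_days, modality = c("T1Gd", "T2"), radius_mm = c(o1, o2))
  }) |> list_rbind()
  mutate(noisy, patient_id = patient_id, .before = 1)
}

#' Noise-free imaging radii of a simulated virtual patient
#'
#' Simulates untreated growth of an established front whose T1Gd edge sits at
#' the spec's initial radius on the first scan (tumors are imaged
#' mid-history, so the front is relaxed before sampling) and returns the
#' exact threshold radii at the scheduled scan times.
#'
#' @inheritParams synthesize_observations
#' @return Tibble: `t_days`, `r_t1`, `r_t2` (mm).
#' @export
simulate_truth_radii <- function(kin, spec, f_t1 = 0.80, f_t2 = 0.16) {
  stopifnot(inherits(kin, "pi_kinetics"), inherits(spec, "cohort_spec"))
  sched <- spec$scan_schedule_days
  span <- max(sched) - min(sched)
  settings <- trial_settings(kin, spec$initial_radius_mm, span + 60)
  curve <- relaxed_radius_curve(kin, spec$initial_radius_mm, max(span, 1),
                                settings,
                                thresholds = c(r_t1 = f_t1, r_t2 = f_t2))
  tibble(
    t_days = sched,
    r_t1 = approx(curve$t_days, curve$r_t1, xout = sched - min(sched))$y,
    r_t2 = approx(curve$t_days, curve$r_t2, xout = sched - min(sched))$y
  )
}

#' Run a virtual clinical trial
#'
#' The full synthetic pipeline: sample a cohort, grow each patient's tumor
#' from the spec's initial radius, apply each arm's therapy, and record per
#' patient and arm the time to a uniform fatal radius (the survival
#' surrogate) and the Days Gained score of a post-treatment scan against
#' the patient's own untreated virtual control. Entirely reproducible from
#' `spec$seed`.
#'
#' Arm descriptors are named lists:
#' * `list(type = "none")` — untreated control;
#' * `list(type = "resection", extent = "GTR"|"STR"|"biopsy", t_days = 0)`;
#' * `list(type = "radiation", alpha = , alpha_beta_ratio = 10, start_day = 0,
#'    dose_Gy = 2, weeks = 6, per_week = 5)` — standard fractionation via
#'    [standard_rt_plan()].
#'
#' @param spec A [cohort_spec()].
#' @param arms Named list of arm descriptors (>= 1).
#' @param fatal_radius_mm Uniform fatal T1Gd-equivalent radius (mm).
#' @param horizon_days Censoring horizon (days).
#' @param dg_scan_day Day of the post-treatment scan scored against the UVC.
#' @param dr,dt Solver resolution for the per-patient simulations.
#' @return A list of class `virtual_trial`: `patients` (one row per patient
#'   x arm: kinetics, stratum inputs, `time_to_fatal_days`, `censored`,
#'   `dg_days`, `post_radius_mm`), `curves` (tibble of per-arm Kaplan-Meier
#'   curves), `spec`, `arms`.
#' @examples
#' \donttest{
#' spec <- cohort_spec(n = 6, seed = 7)
#' trial <- run_virtual_trial(spec,
#'   arms = list(biopsy = list(type = "resection", extent = "biopsy"),
#'               gtr = list(type = "resection", extent = "GTR")))
#' trial$patients
#' }
#' @export
run_virtual_trial <- function(spec, arms, fatal_radius_mm = 35,
                              horizon_days = 4 * DAYS_PER_YEAR,
                              dg_scan_day = 91, dr = 0.25, dt = 1) {
  stopifnot(inherits(spec, "cohort_spec"), is.list(arms), length(arms) >= 1)
  if (is.null(names(arms)) || any(!nzchar(names(arms)))) {
    abort("every arm must be named.")
  }
  patients <- sample_patients(spec)
  rows <- map(seq_len(spec$n), function(i) {
    kin <- kinetics(patients$D[i], patients$rho[i], patients$K[i])
    settings <- trial_settings(kin, max(spec$initial_radius_mm, fatal_radius_mm),
                               horizon_days, dr = dr, dt = dt)
    init <- front_profile_field(kin, spec$initial_radius_mm, settings)
    uvc <- build_uvc(kin, anchor = list(t_days = 0,
                                        radius_mm = spec$initial_radius_mm),
                     horizon_days = horizon_days, mode = "linear")
    imap(arms, function(arm, arm_name) {
      run <- run_patient_arm(kin, init, arm, fatal_radius_mm, horizon_days,
                             settings)
      post_r <- approx(run$traj$t_days, run$traj$radius_mm,
                       xout = min(dg_scan_day, horizon_days), ties = min)$y
      dg <- days_gained(uvc, min(dg_scan_day, horizon_days), max(post_r, 0))
      tibble(patient_id = patients$patient_id[i], arm = arm_name,
             D = kin$D, rho = kin$rho, rho_over_D = rho_over_D(kin),
             velocity = front_velocity(kin),
             time_to_fatal_days = run$ttf$time_to_fatal_days,
             censored = run$ttf$censored,
             post_radius_mm = post_r, dg_days = dg$dg_days,
             dg_saturated = dg$saturated, dg_scan_day = dg$post_t_days)
    }) |> list_rbind()
  }) |> list_rbind()

  curves <- rows |>
    group_by(.data$arm) |>
    dplyr::group_modify(~ kaplan_meier(.x$time_to_fatal_days, !.x$censored)) |>
    ungroup()

  structure(list(patients = rows, curves = curves, spec = spec, arms = arms),
            class = "virtual_trial")
}

# one patient x arm: simulate with therapy events, return trajectory and
# time-to-fatal surrogate
run_patient_arm <- function(kin, init, arm, fatal_radius_mm, horizon_days,
                            settings) {
  type <- arm$type %||% "none"
  events <- switch(
    type,
    none = NULL,
    resection = list(list(
      t_days = arm$t_days %||% 0,
      apply = function(field) {
        apply_resection(field,
                        resection_margin(field, arm$extent %||% "GTR",
                                         str_fraction = arm$str_fraction %||% 0.75),
                        residual_fraction = arm$residual_fraction %||% 0)
      })),
    radiation = {
      plan <- standard_rt_plan(
        alpha = arm$alpha, alpha_beta_ratio = arm$alpha_beta_ratio %||% 10,
        start_day = arm$start_day %||% 0, dose_Gy = arm$dose_Gy %||% 2,
        weeks = arm$weeks %||% 6, per_week = arm$per_week %||% 5)
      map(seq_len(nrow(plan$fractions)), function(j) {
        list(t_days = plan$fractions$t_days[j],
             apply = function(field) apply_fraction(field, plan, j))
      })
    },
    abort(sprintf("unknown arm type '%s'.", type))
  )
  n_save <- max(101, min(401, ceiling(horizon_days / (2 * settings$dt))))
  sim <- pi_simulate(kin, init, duration_days = horizon_days,
                     settings = settings,
                     save_times = seq(0, horizon_days, length.out = n_save),
                     events = events)
  traj <- radius_trajectory(sim)
  hit <- which(traj$radius_mm >= fatal_radius_mm)
  ttf <- if (!length(hit)) {
    surrogate_row(horizon_days, TRUE, fatal_radius_mm)
  } else if (hit[1] == 1) {
    surrogate_row(0, FALSE, fatal_radius_mm, already_fatal = TRUE)
  } else {
    i <- hit[1]
    t_hit <- approx(traj$radius_mm[(i - 1):i], traj$t_days[(i - 1):i],
                    xout = fatal_radius_mm, ties = min)$y
    surrogate_row(t_hit, FALSE, fatal_radius_mm)
  }
  list(traj = traj, ttf = ttf)
}

#' @export
print.virtual_trial <- function(x, ...) {
  cat(sprintf("<virtual_trial> %d patients x %d arm(s): %s\n",
              x$spec$n, length(x$arms), paste(names(x$arms), collapse = ", ")))
  med <- x$patients |>
    group_by(.data$arm) |>
    summarise(median_ttf = median(.data$time_to_fatal_days),
              median_dg = median(.data$dg_days), .groups = "drop")
  print(med)
  invisible(x)
}

#' @export
autoplot.virtual_trial <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(.data$time, .data$survival, color = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "fraction below fatal size",
                  color = "arm") +
    ggplot2::theme_minimal()
}

#' Write the outputs of a virtual trial to a directory
#'
#' Emits `patients.csv` (per patient x arm table), `curves.csv` (per-arm
#' Kaplan-Meier curves) and `summary.json` (arm medians plus a provenance
#' block). All writes are atomic, and the content is a pure function of the
#' spec and arms, so reruns are byte-identical.
#'
#' @param trial A [run_virtual_trial()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "virtual_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_atomic(file.path(dir, "patients.csv"),
               function(p) readr::write_csv(trial$patients, p, progress = FALSE))
  write_atomic(file.path(dir, "curves.csv"),
               function(p) readr::write_csv(trial$curves, p, progress = FALSE))
  summary <- trial$patients |>
    group_by(.data$arm) |>
    summarise(n = n(),
              median_time_to_fatal_days = median(.data$time_to_fatal_days),
              median_days_gained = median(.data$dg_days),
              n_censored = sum(.data$censored), .groups = "drop")
  write_result_json(list(arms = split(summary, summary$arm) |> map(as.list)),
                    file.path(dir, "summary.json"),
                    seed = trial$spec$seed,
                    config = trial$spec[setdiff(names(trial$spec), "seed")])
  invisible(dir)
}
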