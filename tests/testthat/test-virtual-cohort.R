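test_that("cohort sampling is seeded, valid and hits its stated median", {
  spec <- cohort_spec(n = 50, seed = 9)
  a <- sample_patients(spec)
  b <- sample_patients(spec)
  expect_identical(a, b)
  expect_true(all(a$D > 0) && all(a$rho > 0))
  expect_equal(a$velocity, 2 * sqrt(a$D * a$rho))
  # degenerate spread collapses to the medians
  degen <- sample_patients(cohort_spec(n = 5, D_sdlog = 0, rho_sdlog = 0))
  expect_equal(degen$D, rep(25, 5))
  expect_equal(degen$rho, rep(16, 5))
  # law of large numbers on the log-normal median
  big <- sample_patients(cohort_spec(n = 1000, seed = 1))
  expect_equal(median(big$D), 25, tolerance = 0.05)
})

test_that("noiseless synthetic observations equal the simulated threshold radii", {
  k <- kinetics(D = 20, rho = 10)
  spec <- cohort_spec(n = 1, noise_sd_mm = 0, scan_schedule_days = c(0, 120))
  obs <- synthesize_observations(k, spec)
  expect_equal(nrow(obs), 4)
  expect_equal(obs$radius_mm[obs$t_days == 0 & obs$modality == "T1Gd"],
               spec$initial_radius_mm, tolerance = 0.26)
  # paired constraint holds exactly
  wide <- tidyr::pivot_wider(obs, names_from = modality, values_from = radius_mm)
  expect_true(all(wide$T2 >= wide$T1Gd))
})

test_that("noisy observations respect physical constraints", {
  set.seed(31)
  k <- kinetics(D = 4, rho = 25) # sharp front: tight T2-T1 gap stresses resampling
  spec <- cohort_spec(n = 1, noise_sd_mm = 2, scan_schedule_days = c(0, 60, 120))
  for (i in 1:5) {
    obs <- synthesize_observations(k, spec)
    expect_true(all(obs$radius_mm >= 0))
    wide <- tidyr::pivot_wider(obs, names_from = modality,
                               values_from = radius_mm)
    expect_true(all(wide$T2 >= wide$T1Gd))
  }
})

test_that("Kaplan-Meier matches hand-computed product-limit values", {
  # no censoring: survival steps 1 -> 2/3 -> 1/3 -> 0
  km <- kaplan_meier(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(1, 2 / 3, 1 / 3, 0))
  # all censored: flat at 1
  flat <- kaplan_meier(c(5, 8), c(FALSE, FALSE))
  expect_true(all(flat$survival == 1))
  # mixed censoring, worked by hand:
  # times 2, 3+, 4, 5+, 6; S(2) = 4/5, S(4) = 4/5 * 2/3, S(6) = 8/15 * 0
  km2 <- kaplan_meier(c(2, 3, 4, 5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE))
  ev <- km2[km2$n_event > 0, ]
  expect_equal(ev$survival, c(4 / 5, 4 / 5 * 2 / 3, 0))
  expect_true(all(diff(km2$survival) <= 0))
})

test_that("log-rank utility agrees with a known separation", {
  t1 <- c(100, 120, 140, 400, 410, 430)
  ev <- rep(TRUE, 6)
  g <- rep(c("a", "b"), each = 3)
  out <- logrank_test(t1, ev, g)
  expect_lt(out$p_value, 0.05)
})

test_that("a two-arm virtual trial is reproducible and internally consistent", {
  spec <- cohort_spec(n = 4, seed = 21, initial_radius_mm = 14)
  arms <- list(none = list(type = "none"),
               gtr = list(type = "resection", extent = "GTR"))
  t1 <- run_virtual_trial(spec, arms, fatal_radius_mm = 28,
                          horizon_days = 700, dr = 0.5, dt = 1)
  t2 <- run_virtual_trial(spec, arms, fatal_radius_mm = 28,
                          horizon_days = 700, dr = 0.5, dt = 1)
  expect_identical(t1$patients, t2$patients)
  expect_identical(t1$curves, t2$curves)
  # survival-curve validity for every arm
  for (arm in unique(t1$curves$arm)) {
    cv <- t1$curves[t1$curves$arm == arm, ]
    expect_equal(cv$survival[1], 1)
    expect_true(all(diff(cv$survival) <= 1e-12))
  }
  # resection can only help, patient by patient
  wide <- tidyr::pivot_wider(t1$patients[c("patient_id", "arm", "time_to_fatal_days")],
                             names_from = arm, values_from = time_to_fatal_days)
  expect_true(all(wide$gtr >= wide$none))
})

test_that("identical arms produce identical survival curves", {
  spec <- cohort_spec(n = 3, seed = 5, initial_radius_mm = 14)
  arms <- list(a = list(type = "none"), b = list(type = "none"))
  tr <- run_virtual_trial(spec, arms, fatal_radius_mm = 26,
                          horizon_days = 500, dr = 0.5, dt = 1)
  a <- tr$curves[tr$curves$arm == "a", setdiff(names(tr$curves), "arm")]
  b <- tr$curves[tr$curves$arm == "b", setdiff(names(tr$curves), "arm")]
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("generate -> calibrate -> UVC -> Days Gained closes near zero untreated", {
  spec <- cohort_spec(n = 1, seed = 3, noise_sd_mm = 0,
                      scan_schedule_days = c(0, 90, 180, 270))
  k <- kinetics(D = 30, rho = 12)
  obs <- synthesize_observations(k, spec)
  est <- estimate_kinetics(obs)
  t1 <- obs[obs$modality == "T1Gd", ]
  anchor <- t1[t1$t_days == 180, ]
  uvc <- build_uvc(est$kinetics,
                   anchor = list(t_days = anchor$t_days,
                                 radius_mm = anchor$radius_mm),
                   horizon_days = 120, mode = "simulated")
  dg <- days_gained(uvc, 270, t1$radius_mm[t1$t_days == 270])
  expect_lt(abs(dg$dg_days), 6) # calibration + interpolation error budget
})
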