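test_that("linear-quadratic surviving fraction matches independent arithmetic", {
  expect_equal(surviving_fraction(0.34, 0), 1)
  # alpha d + (alpha/10) d^2 at d = 2: 2.4 * alpha
  expect_equal(surviving_fraction(0.340, 2, 10), exp(-2.4 * 0.340),
               tolerance = 1e-15)
  expect_equal(surviving_fraction(0.016, 2, 10), exp(-2.4 * 0.016),
               tolerance = 1e-15)
  expect_error(surviving_fraction(0.3, -1), "non-negative")
})

test_that("radiation_plan validates fractions and derives beta", {
  p <- standard_rt_plan(alpha = 0.34)
  expect_equal(nrow(p$fractions), 30)
  expect_equal(sum(p$fractions$dose_Gy), 60)
  expect_equal(max(p$fractions$t_days), 39) # six weekday-weeks
  expect_equal(p$beta, 0.034)
  expect_error(radiation_plan(tibble::tibble(t_days = c(1, 1), dose_Gy = 2),
                              alpha = 0.3), "increasing")
  expect_error(radiation_plan(tibble::tibble(t_days = 1, dose_Gy = -2),
                              alpha = 0.3), "positive")
})

test_that("a fraction kills density-modulated and respects its edge cases", {
  K <- 1e5
  r <- seq(0, 10, 0.5)
  f <- radial_field(r, rep(0.5 * K, length(r)), K = K)
  plan2 <- radiation_plan(tibble::tibble(t_days = 0, dose_Gy = 2), alpha = 0.34)
  # alpha = 0 -> S = 1 -> untouched
  p0 <- radiation_plan(tibble::tibble(t_days = 0, dose_Gy = 2), alpha = 0)
  expect_equal(apply_fraction(f, p0, 1)$density, f$density)
  # saturated tissue is shielded by the (1 - c/K) factor
  sat <- radial_field(r, rep(K, length(r)), K = K)
  expect_equal(apply_fraction(sat, plan2, 1)$density, sat$density)
  # c = K/2 with S = 1/2 loses a quarter of the kill-eligible half
  S <- surviving_fraction(0.34, 2)
  expect_equal(apply_fraction(f, plan2, 1)$density,
               rep(0.5 * K - (1 - S) * 0.5 * K * 0.5, length(r)))
})

test_that("an empty plan reproduces the untreated simulation bit for bit", {
  k <- ref_kinetics()
  s <- quick_settings()
  init <- front_profile_field(k, 10, s)
  null_plan <- radiation_plan(tibble::tibble(t_days = numeric(),
                                             dose_Gy = numeric()), alpha = 0.34)
  a <- pi_simulate(k, init, 60, settings = s)
  b <- simulate_pirt(k, init, null_plan, 60, settings = s)
  expect_identical(lapply(a$snapshots, `[[`, "density"),
                   lapply(b$snapshots, `[[`, "density"))
})

test_that("post-treatment radius decreases with radiosensitivity alpha", {
  k <- ref_kinetics()
  s <- quick_settings(r_max = 50, dr = 0.5, dt = 1)
  init <- front_profile_field(k, 12, s)
  radii <- vapply(c(0.005, 0.015, 0.04), function(a) {
    sim <- simulate_pirt(k, init, standard_rt_plan(alpha = a), 45, settings = s,
                         save_times = 45)
    extract_radius(sim$snapshots[[length(sim$snapshots)]], 0.80)
  }, numeric(1))
  expect_true(all(diff(radii) < 0))
})

test_that("a very high alpha drives the lesion below its pre-treatment size", {
  k <- ref_kinetics()
  s <- quick_settings(r_max = 50, dr = 0.5, dt = 1)
  init <- front_profile_field(k, 12, s)
  sim <- simulate_pirt(k, init, standard_rt_plan(alpha = 10), 45, settings = s,
                       save_times = 45)
  expect_lt(extract_radius(sim$snapshots[[length(sim$snapshots)]], 0.80), 12)
})

test_that("splitting a dose into sub-fractions raises survival (beta effect)", {
  K <- 1e5
  r <- seq(0, 10, 0.5)
  thin <- radial_field(r, rep(0.01 * K, length(r)), K = K)
  one <- radiation_plan(tibble::tibble(t_days = 0, dose_Gy = 4), alpha = 0.3)
  half <- radiation_plan(tibble::tibble(t_days = 0, dose_Gy = 2), alpha = 0.3)
  after_one <- apply_fraction(thin, one, 1)
  after_two <- apply_fraction(apply_fraction(thin, half, 1), half, 1)
  expect_gt(mean(after_two$density), mean(after_one$density))
})

test_that("PIRT therapy yields a positive Days Gained that grows with alpha", {
  k <- ref_kinetics()
  s <- quick_settings(r_max = 55, dr = 0.5, dt = 1)
  init <- front_profile_field(k, 12, s)
  uvc <- build_uvc(k, anchor = list(t_days = 0, radius_mm = 12),
                   horizon_days = 150, mode = "linear")
  dgs <- vapply(c(0.01, 0.04), function(a) {
    sim <- simulate_pirt(k, init, standard_rt_plan(alpha = a), 100,
                         settings = s, save_times = 100)
    r_post <- extract_radius(sim$snapshots[[length(sim$snapshots)]], 0.80)
    days_gained(uvc, 100, max(r_post, 0.1))$dg_days
  }, numeric(1))
  expect_true(all(dgs > 0))
  expect_gt(dgs[2], dgs[1])
})

test_that("fractions outside the simulated window are rejected", {
  k <- ref_kinetics()
  s <- quick_settings()
  init <- front_profile_field(k, 10, s)
  early <- radiation_plan(tibble::tibble(t_days = -5, dose_Gy = 2), alpha = 0.3)
  late <- radiation_plan(tibble::tibble(t_days = 99, dose_Gy = 2), alpha = 0.3)
  expect_error(simulate_pirt(k, init, early, 50, settings = s), "before")
  expect_error(simulate_pirt(k, init, late, 50, settings = s), "after")
})
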