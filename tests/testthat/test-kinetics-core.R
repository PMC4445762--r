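test_that("kinetics constructor validates and derives wave quantities", {
  k <- kinetics(D = 25, rho = 16)
  expect_equal(front_velocity(k), 40)
  expect_equal(gradient_length(k), 1.25)
  expect_equal(rho_over_D(k), 0.64)
  expect_error(kinetics(D = -1, rho = 1))
  expect_error(kinetics(D = 1, rho = 0))
  expect_error(kinetics(D = 1, rho = 1, K = -5))
})

test_that("logistic reference hits its fixed points and the ln(3) landmark", {
  k <- ref_kinetics()
  t <- c(0, 10, 200)
  expect_equal(logistic_reference(0, k, t), c(0, 0, 0))
  expect_equal(logistic_reference(k$K, k, t), rep(k$K, 3))
  # e^{rho t} = 3 turns c0 = K/2 into 3K/4
  t3 <- log(3) / (k$rho / 365.25)
  expect_equal(logistic_reference(0.5 * k$K, k, t3), 0.75 * k$K)
  expect_error(logistic_reference(2 * k$K, k, 1))
})

test_that("D -> 0 simulation matches the closed-form logistic solution", {
  k <- kinetics(D = 1e-9, rho = 16)
  s <- quick_settings()
  r <- seq(0, s$r_max, s$dr)
  c0 <- 0.3 * k$K * (1 + 0.5 * sin(r)) # spatially varying start
  sim <- pi_simulate(k, radial_field(r, c0, K = k$K), duration_days = 60,
                     settings = s)
  for (f in sim$snapshots[c(2, length(sim$snapshots))]) {
    expected <- logistic_reference(c0, k, attr(f, "t_days"))
    expect_equal(f$density, expected, tolerance = 1e-5)
  }
})

test_that("pure diffusion conserves the volume-weighted cell number", {
  k <- kinetics(D = 25, rho = 1e-15)
  s <- quick_settings(dt = 0.5)
  sim <- pi_simulate(k, gaussian_bolus(k, s), duration_days = 50, settings = s)
  masses <- vapply(sim$snapshots, total_cells, numeric(1))
  expect_lt(max(abs(masses / masses[1] - 1)), 1e-6)
})

test_that("densities stay inside [0, K] throughout a growth simulation", {
  k <- ref_kinetics()
  s <- quick_settings()
  sim <- pi_simulate(k, gaussian_bolus(k, s), duration_days = 365, settings = s)
  for (f in sim$snapshots) {
    expect_gte(min(f$density), 0)
    expect_lte(max(f$density), k$K)
  }
})

test_that("initial density above K and unstable explicit settings are rejected", {
  k <- ref_kinetics()
  s <- quick_settings()
  r <- seq(0, s$r_max, s$dr)
  expect_error(pi_simulate(k, radial_field(r, rep(k$K, length(r)), K = 2 * k$K),
                           duration_days = 10, settings = s),
               "carrying capacity")
  bad <- solver_settings(dr = 0.5, dt = 10, r_max = 60, scheme = "explicit")
  expect_error(pi_simulate(k, gaussian_bolus(k, bad), 10, settings = bad),
               "unstable")
})

test_that("explicit and semi-implicit schemes agree on a smooth problem", {
  k <- kinetics(D = 10, rho = 10)
  # dr^2/(2 D_day) = 0.25/(2*10/365.25) ~ 4.6 days; dt = 0.25 is safely stable
  se <- solver_settings(dr = 0.5, dt = 0.25, r_max = 40, scheme = "explicit")
  si <- solver_settings(dr = 0.5, dt = 0.25, r_max = 40)
  fe <- pi_simulate(k, gaussian_bolus(k, se), 120, settings = se)
  fi <- pi_simulate(k, gaussian_bolus(k, si), 120, settings = si)
  re <- extract_radius(fe$snapshots[[length(fe$snapshots)]], 0.5)
  ri <- extract_radius(fi$snapshots[[length(fi$snapshots)]], 0.5)
  expect_equal(re, ri, tolerance = 0.02)
})

test_that("extract_radius handles step, exponential and empty profiles", {
  K <- 1e5
  r <- seq(0, 20, 0.1)
  step <- radial_field(r, ifelse(r <= 10, K, 0), K = K)
  expect_equal(extract_radius(step, 0.8), 10, tolerance = 0.11)
  expo <- radial_field(r, K * exp(-r / 2), K = K)
  expect_equal(extract_radius(expo, exp(-1)), 2, tolerance = 1e-3)
  empty <- radial_field(r, rep(0, length(r)), K = K)
  expect_equal(extract_radius(empty, 0.3), 0)
})

test_that("outermost crossing is returned for non-monotone profiles", {
  K <- 1
  r <- seq(0, 30, 0.1)
  # two lumps: inner ball plus an outer satellite above threshold
  dens <- pmax(exp(-(r / 4)^2), 0.9 * exp(-((r - 20) / 2)^2))
  f <- radial_field(r, dens, K = K)
  expect_gt(extract_radius(f, 0.5), 20)
})

test_that("wavefront_speed recovers an exact line and rejects boundary hits", {
  traj <- tibble::tibble(t_days = c(0, 0.5, 1) * 365.25,
                         radius_mm = c(10, 20, 30))
  expect_equal(wavefront_speed(traj, fit_fraction = 1), 20)
  k <- ref_kinetics()
  s <- quick_settings(r_max = 25)
  sim <- pi_simulate(k, front_profile_field(k, 10, s), 500, settings = s)
  expect_error(wavefront_speed(sim), "boundary")
})

test_that("front speed converges to 2 sqrt(D rho) and depends only on the product", {
  for (k in list(kinetics(D = 25, rho = 16), kinetics(D = 50, rho = 8))) {
    dur <- 25 / k$rho * 365.25 # rho * t = 25: past the pulled-front transient
    s <- solver_settings(dr = 0.25, dt = 0.5,
                         r_max = 20 + 1.1 * 40 * dur / 365.25)
    sim <- pi_simulate(k, front_profile_field(k, 5, s), dur, settings = s)
    expect_equal(wavefront_speed(sim), 40, tolerance = 0.05)
  }
})

test_that("joint rescaling of (D, rho) rescales the front speed accordingly", {
  s <- solver_settings(dr = 0.25, dt = 0.5, r_max = 110)
  a <- 2
  v1 <- wavefront_speed(pi_simulate(kinetics(D = 25, rho = 16),
                                    front_profile_field(kinetics(D = 25, rho = 16), 5, s),
                                    650, settings = s))
  k2 <- kinetics(D = 25 * a, rho = 16 * a)
  v2 <- wavefront_speed(pi_simulate(k2, front_profile_field(k2, 5, s),
                                    650 / a, settings = s))
  expect_equal(v2 / v1, a, tolerance = 0.03)
})

test_that("radius trajectories and tibble export are consistent", {
  k <- ref_kinetics()
  s <- quick_settings()
  sim <- pi_simulate(k, front_profile_field(k, 8, s), 180, settings = s)
  traj <- radius_trajectory(sim)
  expect_true(all(diff(traj$radius_mm) > -1e-9))
  long <- tibble::as_tibble(sim)
  expect_setequal(unique(long$t_days), traj$t_days)
})
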