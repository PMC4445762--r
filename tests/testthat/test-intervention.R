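test_that("biopsy leaves the field unchanged; a wide margin removes everything", {
  k <- ref_kinetics()
  s <- quick_settings()
  f <- front_profile_field(k, 15, s)
  biopsy <- apply_resection(f, 0)
  expect_equal(biopsy$density, f$density)
  expect_equal(attr(biopsy, "removed_fraction"), 0)
  wide <- apply_resection(f, max(f$r_mm) - s$dr)
  expect_equal(attr(wide, "removed_fraction"), 1, tolerance = 1e-6)
  expect_error(apply_resection(f, max(f$r_mm) + 1), "domain")
})

test_that("removed fraction matches an independent quadrature oracle", {
  K <- 1e5
  r <- seq(0, 40, 0.05)
  f <- radial_field(r, K * pmin(1, exp(-(r - 12) / 3)), K = K)
  margin <- 12
  post <- apply_resection(f, margin)
  # oracle: trapezoid quadrature of 4 pi r^2 c inside/outside the margin
  inside <- quadrature_cells(radial_field(r, ifelse(r <= margin, f$density, 0), K = K))
  expect_equal(attr(post, "removed_fraction"), inside / quadrature_cells(f),
               tolerance = 1e-4)
})

test_that("resection margins resolve by extent", {
  k <- ref_kinetics()
  s <- quick_settings(dr = 0.25)
  f <- front_profile_field(k, 15, s)
  gtr <- resection_margin(f, "GTR")
  expect_equal(gtr, 15, tolerance = s$dr)
  expect_equal(resection_margin(f, "STR"), 0.75 * gtr)
  expect_equal(resection_margin(f, "biopsy"), 0)
})

test_that("the 99% removal margin matches the closed-form ball answer", {
  K <- 1e5
  r <- seq(0, 20, 0.02)
  ball <- radial_field(r, ifelse(r <= 10, K, 0), K = K)
  expect_equal(margin_for_fraction_removed(ball, 0.99), 0.99^(1 / 3) * 10,
               tolerance = 1e-3)
  # fraction -> 1 approaches the outermost nonzero node
  expect_equal(margin_for_fraction_removed(ball, 1 - 1e-9), 10,
               tolerance = 0.06)
  expect_error(margin_for_fraction_removed(ball, 1), "fraction")
  empty <- radial_field(r, rep(0, length(r)), K = K)
  expect_error(margin_for_fraction_removed(empty, 0.5), "no tumor")
})

test_that("nodular tumors hide less beyond the visible edge than diffuse ones", {
  s <- solver_settings(dr = 0.25, dt = 1, r_max = 80)
  gap_for <- function(k) {
    f <- front_profile_field(k, 15, s)
    margin_for_fraction_removed(f, 0.99) - extract_radius(f, 0.80)
  }
  nodular <- gap_for(kinetics(D = 5, rho = 20))   # rho/D = 4
  diffuse <- gap_for(kinetics(D = 50, rho = 5))   # rho/D = 0.1
  expect_lt(nodular, diffuse)
})

test_that("time to fatal radius matches the line inversion in the linear regime", {
  k <- ref_kinetics()
  s <- solver_settings(dr = 0.25, dt = 0.5, r_max = 60)
  init <- front_profile_field(k, 20, s)
  out <- time_to_fatal_radius(k, init, fatal_radius_mm = 30,
                              horizon_days = 400, settings = s)
  expect_false(out$censored)
  expect_equal(out$time_to_fatal_days, 10 / (40 / 365.25), tolerance = 0.05)
  # already fatal
  big <- time_to_fatal_radius(k, init, fatal_radius_mm = 15,
                              horizon_days = 100, settings = s)
  expect_equal(big$time_to_fatal_days, 0)
  expect_true(big$already_fatal)
  # never fatal within horizon -> censored
  cen <- time_to_fatal_radius(k, init, fatal_radius_mm = 55,
                              horizon_days = 30, settings = s)
  expect_true(cen$censored)
})

test_that("survival benefit is monotone in resection margin", {
  k <- ref_kinetics()
  s <- solver_settings(dr = 0.25, dt = 1, r_max = 55)
  init <- front_profile_field(k, 15, s)
  ttf <- vapply(c(0, 8, 15), function(m) {
    time_to_fatal_radius(k, init, fatal_radius_mm = 30,
                         resection = list(t_days = 0, margin_mm = m),
                         horizon_days = 1200, settings = s)$time_to_fatal_days
  }, numeric(1))
  expect_true(all(diff(ttf) > 0))
})

test_that("GTR strictly outlives biopsy on the same patient", {
  k <- ref_kinetics()
  s <- solver_settings(dr = 0.25, dt = 1, r_max = 55)
  init <- front_profile_field(k, 15, s)
  run <- function(extent) {
    time_to_fatal_radius(k, init, fatal_radius_mm = 30,
                         resection = list(t_days = 0, extent = extent),
                         horizon_days = 1500, settings = s)$time_to_fatal_days
  }
  expect_gt(run("GTR"), run("STR"))
  expect_gt(run("STR"), run("biopsy"))
})

test_that("the residual tail regrows with the same asymptotic front speed", {
  k <- ref_kinetics()
  s <- solver_settings(dr = 0.25, dt = 0.5, r_max = 90)
  init <- front_profile_field(k, 15, s)
  post <- apply_resection(init, 15)
  sim <- pi_simulate(k, post, 600, settings = s)
  expect_equal(wavefront_speed(sim), front_velocity(k), tolerance = 0.08)
})
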