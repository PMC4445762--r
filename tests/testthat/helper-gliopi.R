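# shared fixtures: a moderately nodular reference patient and fast solver
# settings sized for unit tests (coarser than production defaults)
ref_kinetics <- function() kinetics(D = 25, rho = 16)

quick_settings <- function(r_max = 60, dr = 0.5, dt = 1) {
  solver_settings(dr = dr, dt = dt, r_max = r_max)
}

# noiseless, model-consistent observation table: linear T1Gd growth at
# velocity v with the T2 edge offset by the steady-front width
linear_obs <- function(v_mm_yr, lambda_mm, r0 = 10, t_days = c(0, 90, 180, 270),
                       f_t1 = 0.80, f_t2 = 0.16) {
  r1 <- r0 + v_mm_yr / 365.25 * t_days
  gap <- lambda_mm * front_width(f_t1, f_t2)
  times <- rep(t_days, each = 2)
  mods <- rep(c("T1Gd", "T2"), length(t_days))
  tibble::tibble(t_days = times, modality = mods,
                 radius_mm = as.vector(rbind(r1, r1 + gap)))
}

# brute-force Youden oracle: direct counting over every candidate threshold,
# written independently of the implementation's vectorized scan
brute_force_threshold <- function(x, pos) {
  u <- sort(unique(x))
  cand <- c(u[1], if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2)
  best <- NULL
  for (thr in cand) {
    sens <- sum(x[pos] < thr) / sum(pos)
    spec <- sum(x[!pos] >= thr) / sum(!pos)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12) {
      best <- list(thr = thr, sens = sens, spec = spec, j = j)
    }
  }
  best
}

# independent quadrature of the total cell number (trapezoid on 4*pi*r^2*c),
# deliberately different from the solver's finite-volume sum
quadrature_cells <- function(field) {
  r <- field$r_mm
  y <- 4 * pi * r^2 * field$density
  sum(diff(r) * (head(y, -1) + tail(y, -1)) / 2)
}
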