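test_that("phase statistics use the n-1 convention and track contributor
           counts", {
  u1 <- matrix(1, 4, 5); u2 <- matrix(-1, 4, 5)
  f1 <- make_vector_field(u1); f2 <- make_vector_field(u2)
  pa <- phase_average(list(f1, f2))
  expect_true(all(pa$u_mean == 0))
  expect_true(all(abs(pa$u_sd - sqrt(2)) < 1e-12))
  expect_true(all(pa$n == 2))
  # identical members: sd identically zero
  pa2 <- phase_average(list(f1, f1, f1))
  expect_true(all(pa2$u_sd == 0))
  # an invalid vector decrements the contributor count, never yields zero
  f3 <- f2
  f3$valid[2, 3] <- FALSE
  pa3 <- phase_average(list(f1, f3))
  expect_equal(pa3$n[2, 3], 1)
  expect_true(is.na(pa3$u_sd[2, 3]))
  expect_equal(pa3$u_mean[2, 3], 1)      # only the valid member contributes
  expect_error(phase_average(list(f1)), "2")
  fbad <- make_vector_field(matrix(0, 3, 3))
  expect_error(phase_average(list(f1, fbad)), "grid")
})

test_that("fluctuation RMS combines the component standard deviations in
           quadrature", {
  set.seed(11)
  mk <- function(su, sv) {
    lapply(1:40, function(i) {
      make_vector_field(matrix(rnorm(20, 0, su), 4, 5),
                        matrix(rnorm(20, 0, sv), 4, 5))
    })
  }
  ens <- mk(3e-3, 4e-3)
  pa <- phase_average(ens)
  r <- rms_fluctuations(pa)
  expect_equal(r, sqrt(pa$u_sd^2 + pa$v_sd^2))
  expect_equal(mean(r), 5e-3, tolerance = 0.15)
  # identical fields: zero; pure x-fluctuation: rms equals sd_x
  expect_true(all(rms_fluctuations(list(ens[[1]], ens[[1]])) == 0))
  ens_x <- mk(3e-3, 0)
  pax <- phase_average(ens_x)
  expect_equal(rms_fluctuations(pax), pax$u_sd)
})

test_that("vorticity reproduces analytic fields", {
  nx <- 21; ny <- 17; dx <- 0.5                    # mm
  xs <- (1:nx) * dx; ys <- (1:ny) * dx
  X <- matrix(rep(xs, each = ny), ny, nx) / 1000    # m
  Y <- matrix(rep(ys, nx), ny, nx) / 1000
  # solid-body rotation at Omega: omega_z = 2*Omega
  Om <- 7
  f <- make_vector_field(-Om * Y, Om * X, dx_mm = dx)
  w <- vorticity(f)
  expect_equal(w[2:(ny - 1), 2:(nx - 1)],
               matrix(2 * Om, ny - 2, nx - 2), tolerance = 1e-9)
  # uniform flow: zero
  expect_true(all(abs(vorticity(make_vector_field(matrix(0.3, ny, nx),
                                                  matrix(0.1, ny, nx),
                                                  dx_mm = dx))) < 1e-12))
  # plane shear u = k*y: omega_z = -k
  k <- 4
  fs <- make_vector_field(k * Y, 0 * Y, dx_mm = dx)
  expect_equal(vorticity(fs)[3, 3], -k, tolerance = 1e-9)
  # curl-free gradient field: u = x, v = y
  fg <- make_vector_field(X, Y, dx_mm = dx)
  expect_lt(max(abs(vorticity(fg))), 1e-9)
  expect_error(vorticity(make_vector_field(matrix(1, 2, 2))), "3x3")
})

test_that("axisymmetric flow-rate integration matches analytic profiles", {
  R <- 0.01
  scale <- 24.6
  ny <- 61
  y_mm <- seq(-10.5, 10.5, length.out = ny)
  mk_field <- function(u_fun) {
    u <- matrix(rep(u_fun(abs(y_mm) / 1000), 4), ny, 4)
    u[abs(y_mm) / 1000 > R] <- NA
    f <- make_vector_field(u, u * 0, dx_mm = 1)
    f$valid <- is.finite(u)
    f$x_mm <- c(8.2, 9.4, 10.6, 11.8); f$y_mm <- y_mm
    f
  }
  uc <- 0.5
  # parabolic: Q = uc * pi R^2 / 2
  fpar <- mk_field(function(r) uc * (1 - (r / R)^2))
  Q <- flow_rate_from_profile(fpar, c(8, 12), R)
  expect_equal(as.numeric(Q), uc * pi * R^2 / 2, tolerance = 5e-3)
  # uniform: Q = u0 pi R^2 (the no-slip endpoint costs a sliver of area)
  funi <- mk_field(function(r) uc + 0 * r)
  expect_equal(as.numeric(flow_rate_from_profile(funi, c(8, 12), R)),
               uc * pi * R^2, tolerance = 2e-2)
  # folded linear profile u = k|r|: Q = 2 pi k R^3 / 3
  kk <- 30
  flin <- mk_field(function(r) kk * r)
  expect_equal(as.numeric(flow_rate_from_profile(flin, c(8, 12), R)),
               2 * pi * kk * R^3 / 3, tolerance = 5e-3)
  expect_error(flow_rate_from_profile(fpar, c(100, 110), R), "outside")
})

test_that("illumination difference maps propagate missing data and report
           the max over valid points", {
  u <- matrix(0.3, 6, 8)
  fA <- make_vector_field(u); fB <- make_vector_field(u)
  d0 <- config_difference(fA, fB)
  expect_true(all(d0[is.finite(d0)] == 0))
  expect_equal(attr(d0, "max_abs"), 0)
  fC <- make_vector_field(u + 0.02)
  dC <- config_difference(fC, fA)
  expect_equal(attr(dC, "max_abs"), 0.02, tolerance = 1e-12)
  fA$valid[1, 1] <- FALSE
  dm <- config_difference(fA, fB)
  expect_true(is.na(dm[1, 1]))
  expect_error(config_difference(fA, make_vector_field(matrix(1, 3, 3))),
               "grids")
})

test_that("flow balance of a rigid loop vanishes and a compliant loop
           stores C_ph * dP/dt", {
  wf <- flow_case_waveform("FM", n = 200)
  wk <- wk3_params(1.5e7, 9e7, 6e-9)
  log_r <- run_loop(wf, wk, hybrid_unit_config(),
                    compliant_segment(C_ph = 0), n_cycles = 4)
  fb <- flow_balance(log_r)
  expect_lt(max(abs(fb$dq_mean)), 1e-12)
  seg <- compliant_segment(C_ph = 2e-9)
  log_c <- run_loop(wf, wk, hybrid_unit_config(), seg, n_cycles = 8)
  fb_c <- flow_balance(log_c)
  # the phase-averaged balance matches the storage computed from the
  # phase-averaged chamber pressure derivative
  p <- log_c$phase$p_chamber_pa_mean
  np <- length(p)
  dpdt <- (p[c(2:np, 1)] - p[c(np, 1:(np - 1))]) * log_c$fs / 2
  expect_equal(fb_c$dq_mean, seg$C_ph * dpdt, tolerance = 0.05)
})

test_that("pressure-strain modulus inverts the strain law", {
  expect_equal(pressure_strain_modulus(5333, 100, 2), 2.67e5,
               tolerance = 2e-3)
  # round trip through the compliant-segment strain
  Ep <- 3.1e5
  dP <- 4000
  delta <- compliant_segment_step(0, dP, 0, compliant_segment(Ep = Ep))$delta[1]
  expect_equal(pressure_strain_modulus(dP, 1, delta), Ep, tolerance = 1e-12)
  expect_equal(pressure_strain_modulus(2 * dP, 1, delta), 2 * Ep)
  expect_error(pressure_strain_modulus(1000, 100, 0), "strain")
  expect_equal(m3s_to_lmin(1e-4), 6)
})
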