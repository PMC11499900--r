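test_that("Windkessel step matches the closed-form linear-ODE solution", {
  wk <- wk3_params(1.5e7, 9e8, 4e-9, P0 = 500)
  dt <- 1 / 5000
  tau <- wk$Rd * wk$C
  # free decay from P0 + 1000 Pa: within 0.1% of the exponential at 5 kHz
  Pc <- wk$P0 + 1000
  for (i in 1:5000) {
    Pc <- wk3_setpoint_step(Pc, 0, wk, dt)$Pc
    expect_equal(Pc - wk$P0, 1000 * exp(-i * dt / tau),
                 tolerance = 1e-3)
  }
  # halving time Rd*C*ln(2)
  n_half <- round(tau * log(2) / dt)
  Pc <- wk$P0 + 1000
  for (i in seq_len(n_half)) Pc <- wk3_setpoint_step(Pc, 0, wk, dt)$Pc
  expect_equal((Pc - wk$P0) / 1000, 0.5, tolerance = 1e-3)
})

test_that("steady flow drives the setpoint to P0 + Q*(Rp+Rd)", {
  wk <- wk3_params(1.5e7, 9e8, 4e-9)
  Pc <- 0; Q <- 1e-5; dt <- 1 / 5000
  for (i in seq_len(30 * 5000)) Pc <- wk3_setpoint_step(Pc, Q, wk, dt)$Pc
  s <- wk3_setpoint_step(Pc, Q, wk, dt)
  expect_equal(s$P_set, Q * (1.5e7 + 9e8), tolerance = 1e-3)
  expect_error(wk3_setpoint_step(0, Q, wk, dt = wk$Rd * wk$C / 2),
               "too coarse")
})

test_that("PID chamber tracks a constant setpoint, saturates on fast ramps,
           and does nothing with zero gains", {
  cfgu <- hybrid_unit_config()
  P <- 0; st <- NULL
  for (i in 1:5000) { h <- hybrid_unit_step(P, 2000, cfgu, st); P <- h$P; st <- h$state }
  expect_lt(abs(P - 2000), 1)
  # ramp steeper than the slew limit: rate pinned, tracking error grows
  cfgs <- hybrid_unit_config(rate_press = 1e4, rate_vac = 1e4)
  P <- 0; st <- NULL; err <- numeric(100)
  for (i in 1:100) {
    sp <- 2e4 * i / 5000 * 10          # 2e5 Pa/s ramp >> 1e4 Pa/s limit
    h <- hybrid_unit_step(P, sp, cfgs, st)
    expect_lte(h$P - P, 1e4 / 5000 + 1e-9)
    err[i] <- sp - h$P
    P <- h$P; st <- h$state
  }
  expect_true(all(diff(err[10:100]) > 0))
  cfg0 <- hybrid_unit_config(kp = 0, ki = 0, kd = 0)
  h <- hybrid_unit_step(1234, 9999, cfg0, NULL)
  expect_equal(h$P, 1234)
})

test_that("compliant segment: rigid limit, analytic sinusoidal storage, and
           the strain law", {
  rigid <- compliant_segment(Ep = 2.67e5, C_ph = 0)
  s <- compliant_segment_step(3e-5, 4000, 1e5, rigid)
  expect_equal(s$Q_out, 3e-5)
  # P = A sin(wt): dQ amplitude = C_ph * w * A
  seg <- compliant_segment(Ep = 2.67e5, C_ph = 2e-9)
  A <- 2000; w <- 2 * pi / 0.8
  tt <- seq(0, 0.8, length.out = 400)
  dq <- seg$C_ph * A * w * cos(w * tt)   # analytic derivative
  got <- vapply(seq_along(tt), function(i) {
    3e-5 - compliant_segment_step(3e-5, A * sin(w * tt[i]),
                                  A * w * cos(w * tt[i]), seg)$Q_out
  }, 0)
  expect_equal(got, dq, tolerance = 1e-12)
  expect_equal(max(abs(got)), seg$C_ph * w * A, tolerance = 1e-6)
  # 40 mmHg excursion on Ep = 2.67e5 N/m^2 gives 2.0% strain
  s2 <- compliant_segment_step(0, 5333, 0, compliant_segment(Ep = 2.67e5),
                               P_dia = 0)
  expect_equal(s2$delta[1], 0.02, tolerance = 2e-3)   # 40 mmHg -> 2.0% strain
})

test_that("loop simulation is phase-repeatable without noise and applies
           the configured flowmeter delay", {
  wf <- flow_case_waveform("FL", n = 200)
  # short load time constant (Rd*C = 0.36 s) so the start-up transient has
  # decayed within the first half of the run
  wk <- wk3_params(1.5e7, 9e7, 4e-9)
  log <- run_loop(wf, wk, hybrid_unit_config(), compliant_segment(),
                  n_cycles = 8, fs = 5000, delay = 0.023)
  expect_equal(max(log$phase$q_in_m3s_sd), 0, tolerance = 1e-12)
  expect_lt(max(log$phase$p_chamber_pa_sd), 2)
  # delay of the logged flow vs the true pump flow, by cross-correlation
  qa <- log$data$q_in_m3s; qt <- log$truth$q_in_m3s
  lags <- 0:200
  cc <- vapply(lags, function(L) {
    n <- length(qa)
    sum(qt[1:(n - L)] * qa[(1 + L):n])
  }, 0)
  expect_equal(lags[which.max(cc)] / 5000, 0.023, tolerance = 1e-6)
})

test_that("volume is conserved over whole cycles and the rigid loop passes
           the inlet flow through unchanged", {
  wf <- flow_case_waveform("FM", n = 200)
  wk <- wk3_params(1.5e7, 9e7, 6e-9)   # settles within the first cycles
  rigid <- compliant_segment(C_ph = 0)
  log <- run_loop(wf, wk, hybrid_unit_config(), rigid, n_cycles = 3)
  expect_equal(log$data$q_in_m3s, log$data$q_out1_m3s, tolerance = 1e-15)
  seg <- compliant_segment(C_ph = 2e-9)
  log2 <- run_loop(wf, wk, hybrid_unit_config(), seg, n_cycles = 8)
  # cycle-integrated storage vanishes once the pressure is periodic (skip
  # the start-up transient)
  sel <- log2$data$time_s >= 4 * 0.8
  dq <- log2$truth$q_in_m3s[sel] - log2$truth$q_out1_m3s[sel]
  q_scale <- max(abs(log2$truth$q_in_m3s))
  expect_lt(abs(mean(dq)) / q_scale, 5e-4)
})

test_that("Windkessel parameters are recovered within 5% from a noisy
           pressure/flow record at 30 dB SNR", {
  set.seed(99)
  wf <- flow_case_waveform("FL", n = 200)
  wk_true <- wk3_params(1.5e7, 9e8, 4e-9)
  dt <- 1 / 500                       # decimated record is enough for a fit
  tt <- seq(0, 4 * 0.8, by = dt)
  Q <- waveform_eval(wf, tt)
  Pc <- 0; P <- numeric(length(Q))
  for (i in seq_along(Q)) {
    s <- wk3_setpoint_step(Pc, Q[i], wk_true, dt)
    Pc <- s$Pc; P[i] <- s$P_set
  }
  snr_amp <- sqrt(mean(P^2)) / 10^(30 / 20)
  Pn <- P + rnorm(length(P), 0, snr_amp)
  fit <- wk3_fit(Q, Pn, dt)
  expect_equal(fit$Rp, wk_true$Rp, tolerance = 0.05)
  expect_equal(fit$Rd, wk_true$Rd, tolerance = 0.05)
  expect_equal(fit$C, wk_true$C, tolerance = 0.05)
})

test_that("diverging loop configurations raise an error naming the step", {
  wf <- flow_case_waveform("FL", n = 100)
  wk <- wk3_params(1.5e7, 9e8, 4e-9)
  bad <- hybrid_unit_config(kp = 1e9, ki = 1e12, rate_press = 1e15,
                            rate_vac = 1e15)
  expect_error(run_loop(wf, wk, bad, compliant_segment(), n_cycles = 1),
               "diverged|step")
})
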