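#' Three-element Windkessel parameters
#'
#' Lumped model of the arterial load downstream of an outlet: a proximal
#' resistance Rp in series with a parallel capacitance C / distal resistance
#' Rd pair referenced to a ground pressure P0.
#'
#' @param Rp proximal resistance, kg m^-4 s^-1.
#' @param Rd distal resistance, kg m^-4 s^-1.
#' @param C capacitance, m^4 s^2 kg^-1.
#' @param P0 ground pressure, Pa.
#' @return object of class \code{wk3_params}.
#' @export
wk3_params <- function(Rp, Rd, C, P0 = 0) {
  stopifnot(Rp > 0, Rd > 0, C > 0)
  structure(list(Rp = Rp, Rd = Rd, C = C, P0 = P0), class = "wk3_params")
}

#' One step of the Windkessel setpoint law
#'
#' Advances the capacitor pressure of a 3-element Windkessel by one time step
#' under the instantaneous flow Q and returns the new state together with the
#' pressure setpoint commanded to the hybrid unit:
#' \deqn{\frac{dP_c}{dt} = \frac{1}{C}\left(Q - \frac{P_c - P_0}{R_d}\right),
#'   \qquad P_{set} = P_c + Q R_p.}
#' The update is the trapezoidal rule, which is exact to second order and
#' unconditionally stable for this linear ODE; a guard still rejects steps
#' that are coarse relative to the time constant \eqn{R_d C}.
#'
#' @param Pc capacitor pressure, Pa.
#' @param Q instantaneous flow, m^3/s.
#' @param params a \code{\link{wk3_params}}.
#' @param dt step, s; must satisfy \code{dt < Rd*C/100}.
#' @return list with \code{Pc} (new capacitor pressure, Pa) and \code{P_set}
#'   (setpoint, Pa).
#' @export
wk3_setpoint_step <- function(Pc, Q, params, dt) {
  stopifnot(inherits(params, "wk3_params"), dt > 0)
  tau <- params$Rd * params$C
  if (dt >= tau / 100) {
    stop(sprintf("step dt = %g s too coarse for Windkessel time constant Rd*C = %g s",
                 dt, tau))
  }
  a <- dt / (2 * tau)
  Pc_new <- (Pc * (1 - a) + dt * Q / params$C + 2 * a * params$P0) / (1 + a)
  list(Pc = Pc_new, P_set = Pc_new + Q * params$Rp)
}

#' Hybrid pressure-chamber configuration
#'
#' The hybrid unit is an air chamber whose pressure is driven toward the
#' Windkessel setpoint by a PID controller actuating solenoid valves on a
#' pressure line and a vacuum line. The valves limit how fast the chamber
#' pressure can slew in either direction.
#'
#' @param kp,ki,kd PID gains; the controller output has units Pa/s so
#'   \code{kp} is 1/s, \code{ki} 1/s^2, \code{kd} dimensionless.
#' @param rate_press maximum pressurization rate (toward the 3 kPa pressure
#'   line), Pa/s.
#' @param rate_vac maximum depressurization rate (toward the -0.5 kPa vacuum
#'   line), Pa/s, given as a positive magnitude.
#' @param dt control step, s.
#' @return object of class \code{hybrid_unit_config}.
#' @export
hybrid_unit_config <- function(kp = 400, ki = 4000, kd = 0,
                               rate_press = 4e5, rate_vac = 4e5,
                               dt = 1 / 5000) {
  stopifnot(kp >= 0, ki >= 0, kd >= 0, rate_press > 0, rate_vac > 0, dt > 0)
  structure(list(kp = kp, ki = ki, kd = kd, rate_press = rate_press,
                 rate_vac = rate_vac, dt = dt),
            class = "hybrid_unit_config")
}

#' One PID step of the hybrid pressure chamber
#'
#' Advances the chamber pressure one control step toward the setpoint. The
#' chamber is modeled as a rate-limited integrator: the PID output is a
#' commanded pressure slew (Pa/s) clipped to the line/vacuum limits. Integral
#' action uses clamping anti-windup (the integrator freezes while the
#' actuator is saturated in the direction that would deepen saturation).
#'
#' @param P chamber pressure, Pa.
#' @param P_set setpoint, Pa.
#' @param config a \code{\link{hybrid_unit_config}}.
#' @param state controller state, list with \code{integral} and
#'   \code{prev_err}; pass \code{NULL} to initialize.
#' @param dt step, s (defaults to the config control step).
#' @return list with \code{P} (new chamber pressure), \code{state} (updated
#'   controller state) and \code{saturated} (logical).
#' @export
hybrid_unit_step <- function(P, P_set, config, state = NULL, dt = config$dt) {
  stopifnot(inherits(config, "hybrid_unit_config"), dt > 0)
  if (is.null(state)) state <- list(integral = 0, prev_err = NULL)
  err <- P_set - P
  deriv <- if (is.null(state$prev_err)) 0 else (err - state$prev_err) / dt
  integral_cand <- state$integral + err * dt
  u <- config$kp * err + config$ki * integral_cand + config$kd * deriv
  u_clipped <- min(max(u, -config$rate_vac), config$rate_press)
  saturated <- u != u_clipped
  # anti-windup: keep the old integral if saturation would deepen
  if (saturated && sign(u - u_clipped) == sign(err)) {
    integral_cand <- state$integral
    u <- config$kp * err + config$ki * integral_cand + config$kd * deriv
    u_clipped <- min(max(u, -config$rate_vac), config$rate_press)
  }
  list(P = P + u_clipped * dt,
       state = list(integral = integral_cand, prev_err = err),
       saturated = saturated)
}

#' Compliant phantom segment
#'
#' Lumped description of the deformable phantom: a pressure-strain elastic
#' modulus Ep governing wall strain, and a volumetric compliance C_ph that
#' buffers flow between inlet and outlet.
#'
#' @param Ep pressure-strain elastic modulus, N/m^2.
#' @param C_ph lumped volumetric compliance, m^4 s^2 kg^-1 (0 = rigid).
#' @param ref_diameter reference (diastolic) diameter per axial station, mm.
#' @return object of class \code{compliant_segment}.
#' @export
compliant_segment <- function(Ep = 3e5, C_ph = 2e-9,
                              ref_diameter = c(20, 35, 32)) {
  stopifnot(Ep > 0, C_ph >= 0, all(ref_diameter > 0))
  structure(list(Ep = Ep, C_ph = C_ph, ref_diameter = ref_diameter),
            class = "compliant_segment")
}

#' One step of the compliant segment
#'
#' Flow storage and wall strain of the deformable phantom:
#' \deqn{Q_{out} = Q_{in} - C_{ph}\, dP/dt, \qquad
#'   \delta = (P - P_{dia}) / E_p,}
#' where \eqn{\delta} is the relative circumferential strain at each axial
#' station (fraction; multiply by the station reference diameter for an
#' absolute diameter change).
#'
#' @param Q_in inlet flow, m^3/s.
#' @param P segment pressure, Pa.
#' @param dPdt pressure rate, Pa/s.
#' @param seg a \code{\link{compliant_segment}}.
#' @param P_dia diastolic reference pressure, Pa.
#' @return list with \code{Q_out} (m^3/s) and \code{delta} (strain fraction
#'   per station).
#' @export
compliant_segment_step <- function(Q_in, P, dPdt, seg, P_dia = 0) {
  stopifnot(inherits(seg, "compliant_segment"))
  list(Q_out = Q_in - seg$C_ph * dPdt,
       delta = rep((P - P_dia) / seg$Ep, length(seg$ref_diameter)))
}

#' Simulate the hybrid mock circulatory loop
#'
#' Runs the closed loop at the sensor logging rate: the pump imposes the flow
#' waveform, the Windkessel law turns the latest (delayed) flow measurement
#' into a pressure setpoint, the PID-regulated chamber tracks it under slew
#' limits, and the compliant phantom stores flow in proportion to the chamber
#' pressure rate. Flow channels are logged through the flowmeter delay, and
#' optional Gaussian sensor noise is added to all channels.
#'
#' @param pump a \code{\link{flow_waveform}}.
#' @param wk a \code{\link{wk3_params}} (single outlet).
#' @param unit a \code{\link{hybrid_unit_config}}.
#' @param seg a \code{\link{compliant_segment}}.
#' @param n_cycles number of cardiac cycles to simulate.
#' @param fs logging frequency, Hz.
#' @param delay flowmeter delay, s (applied to the flow channels as logged;
#'   calibrated on the real rig between 20 and 26 ms).
#' @param noise_sd named list of Gaussian noise standard deviations:
#'   \code{q} (m^3/s) for flow channels, \code{p} (Pa) for pressure channels.
#' @param seed RNG seed for the sensor noise.
#' @param R_inlet resistive drop between inlet pressure tap and chamber,
#'   kg m^-4 s^-1 (plumbing, for the logged inlet-pressure channel only).
#' @return object of class \code{sensor_log}: a list with \code{data} (a
#'   data.frame: time_s, q_in_m3s, q_out1_m3s, p_chamber_pa, p_in_pa,
#'   p_out_pa, p_set_pa, delta per station), \code{phase} (phase-averaged
#'   mean and sd over the last half of the cycles, on the 0..T phase grid),
#'   and metadata (\code{fs}, \code{period}, \code{n_cycles}, \code{delay},
#'   \code{seed}).
#' @export
run_loop <- function(pump, wk, unit, seg, n_cycles = 10, fs = 5000,
                     delay = 0.023, noise_sd = list(q = 0, p = 0),
                     seed = NULL, R_inlet = 1e6) {
  stopifnot(inherits(pump, "flow_waveform"), inherits(wk, "wk3_params"),
            inherits(unit, "hybrid_unit_config"),
            inherits(seg, "compliant_segment"), n_cycles >= 1, fs > 0)
  dt <- 1 / fs
  Tcyc <- pump$period
  n <- as.integer(round(n_cycles * Tcyc * fs))
  tt <- (seq_len(n) - 1) * dt
  q_pump <- waveform_eval(pump, tt)
  ndel <- as.integer(round(delay * fs))

  Pc <- wk$P0
  Pch <- wk$P0
  st <- NULL
  q_out <- numeric(n); p_ch <- numeric(n); p_set <- numeric(n)
  dPdt_prev <- 0
  for (i in seq_len(n)) {
    # latest delayed flow measurement drives the setpoint law
    i_meas <- max(1L, i - ndel)
    s <- wk3_setpoint_step(Pc, q_pump[i_meas], wk, dt)
    Pc <- s$Pc; p_set[i] <- s$P_set
    h <- hybrid_unit_step(Pch, p_set[i], unit, st, dt)
    dPdt <- (h$P - Pch) / dt
    Pch <- h$P; st <- h$state
    p_ch[i] <- Pch
    cs <- compliant_segment_step(q_pump[i], Pch, dPdt, seg)
    q_out[i] <- cs$Q_out
    if (!is.finite(Pc) || !is.finite(Pch) || abs(Pch) > 1e10) {
      stop(sprintf("loop state diverged at step %d (dt = %g s); reduce gains or step",
                   i, dt))
    }
  }
  first_cycle <- if (n_cycles == 1) 0 else ceiling(n_cycles / 2)
  P_dia <- stats::quantile(p_ch[tt >= first_cycle * Tcyc - 1e-12], 0.02,
                           names = FALSE)
  delta <- outer((p_ch - P_dia) / seg$Ep, rep(1, length(seg$ref_diameter)))
  colnames(delta) <- sprintf("delta_%d", seq_along(seg$ref_diameter))

  delay_ch <- function(x) x[pmax(1L, seq_len(n) - ndel)]
  if (!is.null(seed)) set.seed(seed)
  nz <- function(sd, m) if (sd > 0) stats::rnorm(m, 0, sd) else 0
  d <- data.frame(
    time_s = tt,
    q_in_m3s = delay_ch(q_pump) + nz(noise_sd$q, n),
    q_out1_m3s = delay_ch(q_out) + nz(noise_sd$q, n),
    p_chamber_pa = p_ch + nz(noise_sd$p, n),
    p_in_pa = p_ch + R_inlet * q_pump + nz(noise_sd$p, n),
    p_out_pa = p_ch + nz(noise_sd$p, n),
    p_set_pa = p_set
  )
  d <- cbind(d, delta)

  # phase statistics over the last half of the cycles
  sel <- tt >= first_cycle * Tcyc - 1e-12
  spc <- as.integer(round(Tcyc * fs))
  phase_idx <- ((seq_len(n) - 1) %% spc) + 1L
  chans <- setdiff(names(d), "time_s")
  phase <- list(time_s = (seq_len(spc) - 1) * dt)
  for (ch in chans) {
    sp <- split(d[[ch]][sel], phase_idx[sel])
    phase[[paste0(ch, "_mean")]] <- vapply(sp, mean, 0)
    phase[[paste0(ch, "_sd")]] <- vapply(
      sp, function(v) if (length(v) > 1) stats::sd(v) else 0, 0)
  }
  structure(list(data = d, phase = as.data.frame(phase),
                 fs = fs, period = Tcyc, n_cycles = n_cycles,
                 delay = delay, seed = seed,
                 truth = data.frame(time_s = tt, q_in_m3s = q_pump,
                                    q_out1_m3s = q_out)),
            class = "sensor_log")
}

#' Write / read a sensor log as CSV
#' @param log a \code{sensor_log}.
#' @param path CSV path.
#' @export
write_sensor_log_csv <- function(log, path) {
  stopifnot(inherits(log, "sensor_log"))
  utils::write.csv(log$data, path, row.names = FALSE)
  invisible(path)
}

#' Fit 3-element Windkessel parameters to a pressure/flow pair
#'
#' Least-squares recovery of (Rp, Rd, C) from a measured setpoint-pressure
#' trace and the flow that produced it, by simulating the setpoint law over
#' the flow record and minimizing the squared pressure residual on a log
#' parameter scale (Nelder-Mead).
#'
#' @param Q flow samples, m^3/s.
#' @param P pressure samples, Pa (the Windkessel setpoint response to Q).
#' @param dt sample step, s.
#' @param P0 ground pressure, Pa (assumed known).
#' @param init initial guess, list/vector of Rp, Rd, C.
#' @return a \code{\link{wk3_params}} with the fitted values plus attribute
#'   \code{rss}.
#' @export
wk3_fit <- function(Q, P, dt, P0 = 0, init = c(Rp = 1e7, Rd = 5e8, C = 5e-9)) {
  stopifnot(length(Q) == length(P), dt > 0)
  simulate <- function(par) {
    wk <- wk3_params(par[1], par[2], par[3], P0)
    Pc <- P[1] - Q[1] * par[1]
    out <- numeric(length(Q))
    for (i in seq_along(Q)) {
      s <- wk3_setpoint_step(Pc, Q[i], wk, dt)
      Pc <- s$Pc; out[i] <- s$P_set
    }
    out
  }
  obj <- function(lp) {
    par <- exp(lp)
    sum((simulate(par) - P)^2)
  }
  fit <- stats::optim(log(unlist(init)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  par <- unname(exp(fit$par))
  out <- wk3_params(par[1], par[2], par[3], P0)
  attr(out, "rss") <- fit$value
  out
}
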