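#' Working-fluid properties
#'
#' Blood-analog fluid used in the phantom loop: a water/glycerol/urea mixture
#' matching both the refractive index of the silicone phantom and the
#' viscosity and density of blood.
#'
#' @param kinematic_viscosity kinematic viscosity, mm^2/s.
#' @param density fluid density, kg/m^3. The default is a typical blood-analog
#'   value; the density enters only through pressure-gradient bookkeeping and
#'   never the velocity solutions, which are driven by flow-rate matching.
#' @return object of class \code{fluid_properties}.
#' @export
fluid_properties <- function(kinematic_viscosity = 3.82, density = 1060) {
  stopifnot(kinematic_viscosity > 0, density > 0)
  structure(list(kinematic_viscosity = kinematic_viscosity, density = density),
            class = "fluid_properties")
}

#' Periodic flow waveform
#'
#' Container for a periodic volumetric flow waveform Q(t): one period of
#' samples plus its truncated Fourier representation.
#'
#' @param time sample times, s, covering [0, T).
#' @param flow volumetric flow at each sample, m^3/s.
#' @param period cycle period T, s.
#' @param n_harmonics number of oscillatory harmonics retained in the Fourier
#'   representation (the mean is always kept).
#' @return object of class \code{flow_waveform} with fields \code{period},
#'   \code{time}, \code{flow}, and \code{harmonics} (complex vector,
#'   element k+1 = harmonic k; harmonic 0 is the real-valued mean flow).
#' @seealso \code{\link{fourier_decompose}}, \code{\link{waveform_eval}}
#' @export
flow_waveform <- function(time, flow, period, n_harmonics = 12) {
  stopifnot(period > 0, length(time) == length(flow), length(flow) >= 3)
  if (any(time < 0) || any(time >= period)) {
    stop("sample times must cover [0, T)")
  }
  h <- fourier_decompose(time, flow, period, n_harmonics)
  structure(list(period = period, time = time, flow = flow, harmonics = h),
            class = "flow_waveform")
}

#' Fourier decomposition of a periodic signal
#'
#' Computes complex harmonic coefficients c_k, k = 0..n, such that the signal
#' is reconstructed as \eqn{Q(t) = Re\{\sum_k c_k e^{i 2\pi k t / T}\}}.
#' Coefficient 0 is the (real) mean. Non-uniformly sampled input is resampled
#' by periodic linear interpolation before the FFT.
#'
#' @param time sample times, s, in [0, T).
#' @param x signal values at \code{time}.
#' @param period period T, s.
#' @param n_harmonics number of oscillatory harmonics to keep; requires at
#'   least \code{2 * n_harmonics + 1} samples.
#' @return complex vector of length \code{n_harmonics + 1}.
#' @export
fourier_decompose <- function(time, x, period, n_harmonics = 12) {
  stopifnot(period > 0, n_harmonics >= 0)
  n <- length(x)
  if (n < 2 * n_harmonics + 1) {
    stop("need at least 2*n_harmonics+1 samples per period")
  }
  o <- order(time)
  time <- time[o]; x <- x[o]
  dt <- diff(time)
  uniform <- n >= 2 && diff(range(dt)) < 1e-9 * period &&
    abs(time[1]) < 1e-12 && abs(time[n] + dt[1] - period) < 1e-6 * period
  if (!uniform) {
    # periodic linear interpolation onto a uniform grid
    m <- max(256L, 4L * n_harmonics + 1L)
    tt <- c(time, time[1] + period)
    xx <- c(x, x[1])
    tu <- (seq_len(m) - 1) * period / m
    x <- stats::approx(tt, xx, xout = tu, rule = 2)$y
    n <- m
  }
  f <- stats::fft(x) / n
  k <- seq_len(min(n_harmonics, floor((n - 1) / 2)))
  c(Re(f[1]), 2 * f[1 + k])
}

#' Evaluate a flow waveform from its harmonics
#'
#' @param wf a \code{flow_waveform} (or a bare complex harmonic vector, in
#'   which case \code{period} must be given).
#' @param t times, s (any values; the waveform is periodic).
#' @param period period T, s, if \code{wf} is a bare harmonic vector.
#' @return flow Q(t), m^3/s, same length as \code{t}.
#' @export
waveform_eval <- function(wf, t, period = NULL) {
  if (inherits(wf, "flow_waveform")) {
    h <- wf$harmonics; period <- wf$period
  } else {
    h <- wf
    if (is.null(period)) stop("period required for a bare harmonic vector")
  }
  k <- seq_along(h) - 1
  ph <- outer(t, k, function(tt, kk) exp(2i * pi * kk * tt / period))
  as.numeric(Re(ph %*% h))
}

#' Dimensionless flow numbers
#'
#' Peak Reynolds, time-averaged Reynolds and Womersley numbers of a pulsatile
#' flow in a circular tube:
#' \deqn{Re_{max} = U_{max} d / \nu, \quad \langle Re\rangle = \langle U\rangle d/\nu,
#'   \quad \alpha = \frac{d}{2}\sqrt{\frac{2\pi}{T\nu}},}
#' with velocities derived from the flow rate through the cross-section area.
#' The time-averaged velocity uses |Q| by default, so that the brief valve
#' regurgitation backflow contributes its magnitude; set
#' \code{signed_mean = TRUE} for the signed mean.
#'
#' @param waveform a \code{\link{flow_waveform}}.
#' @param d tube inner diameter, m.
#' @param fluid a \code{\link{fluid_properties}}.
#' @param signed_mean use the signed rather than absolute mean velocity.
#' @return list with \code{Re_max}, \code{Re_mean}, \code{alpha},
#'   \code{U_max} (m/s), \code{U_mean} (m/s) and \code{d} (m).
#' @examples
#' wf <- flow_case_waveform("FL")
#' dimensionless_numbers(wf, d = 0.02, fluid_properties())
#' @export
dimensionless_numbers <- function(waveform, d, fluid, signed_mean = FALSE) {
  stopifnot(inherits(waveform, "flow_waveform"), d > 0,
            inherits(fluid, "fluid_properties"))
  area <- pi * d^2 / 4
  if (area <= 0 || length(waveform$flow) == 0) stop("zero-area or empty waveform")
  nu <- fluid$kinematic_viscosity * 1e-6    # mm^2/s -> m^2/s
  # the stored samples carry the un-truncated waveform
  u <- waveform$flow / area
  U_max <- max(u)
  U_mean <- if (signed_mean) mean(u) else mean(abs(u))
  list(Re_max = U_max * d / nu,
       Re_mean = U_mean * d / nu,
       alpha = (d / 2) * sqrt(2 * pi / (waveform$period * nu)),
       U_max = U_max, U_mean = U_mean, d = d)
}

# Bessel functions of the first kind for complex argument, by power series.
# Arguments here are i^{3/2} * alpha_k with alpha_k <= ~50, for which the
# series is accurate in double precision (worst-case cancellation amplifies
# rounding by ~e^{0.3|z|}, i.e. <= ~1e6 relative on 1e-16 terms).
besselJ0_complex <- function(z) {
  out <- z * 0 + 1
  term <- out
  zz <- -(z / 2)^2
  for (m in 1:160) {
    term <- term * zz / m^2
    out <- out + term
    if (all(Mod(term) < 1e-18 * (Mod(out) + 1))) break
  }
  out
}

besselJ1_complex <- function(z) {
  term <- z / 2
  out <- term
  zz <- -(z / 2)^2
  for (m in 1:160) {
    term <- term * zz / (m * (m + 1))
    out <- out + term
    if (all(Mod(term) < 1e-18 * (Mod(out) + 1))) break
  }
  out
}

#' Womersley pulsatile velocity profile from flow harmonics
#'
#' Analytic axial velocity u(r, t) of fully developed pulsatile flow in a
#' rigid circular tube, built harmonic by harmonic. Harmonic 0 contributes
#' the Poiseuille profile of the mean flow; each oscillatory harmonic k
#' contributes the classical Bessel-function solution
#' \deqn{u_k(r,t) = Re\left\{\frac{c_k}{A}\,
#'   \frac{1 - J_0(\Lambda_k r/R)/J_0(\Lambda_k)}
#'        {1 - 2 J_1(\Lambda_k)/(\Lambda_k J_0(\Lambda_k))}\, e^{i k \omega t}\right\},}
#' with \eqn{\Lambda_k = i^{3/2} \alpha \sqrt{k}} and the amplitude chosen so
#' that the cross-sectional integral of each harmonic reproduces that harmonic
#' of the flow waveform (A is the tube cross-section area). Summing harmonics
#' therefore reproduces Q(t) exactly up to truncation.
#'
#' @param harmonics complex harmonic vector (element k+1 = harmonic k), as
#'   produced by \code{\link{fourier_decompose}}, units m^3/s; or a
#'   \code{flow_waveform}, in which case \code{period} is taken from it.
#' @param d tube inner diameter, m.
#' @param fluid a \code{\link{fluid_properties}}.
#' @param period cycle period T, s.
#' @param r radial positions, m, |r| <= d/2.
#' @param t times, s (vectorized).
#' @return matrix of axial velocity, m/s, \code{length(r)} rows by
#'   \code{length(t)} columns (dropped to a vector if either has length 1).
#' @examples
#' fl <- fluid_properties()
#' wf <- flow_case_waveform("FH")
#' r <- seq(-0.01, 0.01, length.out = 81)
#' u <- womersley_profile(wf, d = 0.02, fl, r = r, t = 0.12)
#' @export
womersley_profile <- function(harmonics, d, fluid, period = NULL, r, t) {
  if (inherits(harmonics, "flow_waveform")) {
    period <- harmonics$period
    harmonics <- harmonics$harmonics
  }
  stopifnot(d > 0, inherits(fluid, "fluid_properties"), period > 0)
  R <- d / 2
  if (any(abs(r) > R * (1 + 1e-12))) stop("radial position outside the tube")
  if (any(!is.finite(harmonics))) stop("harmonics must be finite")
  nu <- fluid$kinematic_viscosity * 1e-6
  area <- pi * R^2
  omega <- 2 * pi / period
  rr <- pmin(abs(r), R)
  u <- matrix(0, length(r), length(t))
  # harmonic 0: Poiseuille
  u0 <- 2 * (Re(harmonics[1]) / area) * (1 - (rr / R)^2)
  u <- u + outer(u0, rep(1, length(t)))
  if (length(harmonics) > 1) {
    for (k in seq_len(length(harmonics) - 1)) {
      ck <- harmonics[k + 1]
      if (ck == 0) next
      alpha_k <- R * sqrt(k * omega / nu)
      Lam <- complex(modulus = alpha_k, argument = 3 * pi / 4)  # i^{3/2} alpha
      J0L <- besselJ0_complex(Lam)
      shape <- (1 - besselJ0_complex(Lam * rr / R) / J0L) /
        (1 - 2 * besselJ1_complex(Lam) / (Lam * J0L))
      u <- u + Re(outer(shape, exp(1i * k * omega * t)) * (ck / area))
    }
  }
  if (length(r) == 1 || length(t) == 1) drop(u) else u
}

#' Cross-sectional flow rate of a radial velocity profile
#'
#' Trapezoidal evaluation of \eqn{Q = 2\pi \int_0^R u(r)\, r\, dr} for a
#' profile sampled on radii \code{r} (m).
#'
#' @param r radii, m, non-negative, increasing.
#' @param u axial velocity at \code{r}, m/s (vector, or matrix with rows
#'   matching \code{r}).
#' @return flow rate, m^3/s (scalar or one per column of \code{u}).
#' @export
profile_flow_rate <- function(r, u) {
  stopifnot(all(r >= 0), !is.unsorted(r))
  if (is.matrix(u)) {
    apply(u, 2, function(col) profile_flow_rate(r, col))
  } else {
    2 * pi * sum(diff(r) * (utils::head(u * r, -1) + utils::tail(u * r, -1)) / 2)
  }
}

# Loop and flow-profile operating table for the idealized phantom:
# 3-element-Windkessel parameters (SI), peak and time-averaged inlet
# velocities (m/s) for the low/medium/high flow amplitudes.
.flow_case_table <- list(
  FL = list(Rp = 1.5e7, C = 4e-9, Rd = 9e8,   U_max = 0.26, U_mean = 0.06),
  FM = list(Rp = 1.5e7, C = 6e-9, Rd = 4.5e8, U_max = 0.44, U_mean = 0.09),
  FH = list(Rp = 1.2e7, C = 8e-9, Rd = 4e8,   U_max = 0.54, U_mean = 0.11)
)

#' Operating parameters of an idealized flow case
#'
#' Returns the Windkessel parameters and velocity targets of one of the three
#' idealized-phantom flow amplitudes (FL low, FM medium, FH high).
#'
#' @param case one of "FL", "FM", "FH".
#' @return list with \code{Rp}, \code{C}, \code{Rd} (SI), \code{U_max},
#'   \code{U_mean} (m/s).
#' @export
flow_case_params <- function(case = c("FL", "FM", "FH")) {
  case <- match.arg(case)
  .flow_case_table[[case]]
}

#' Parameterized pump waveform for an idealized flow case
#'
#' The loop's piston pump produces a systolic ejection followed by a brief
#' regurgitation dip as the mechanical valve closes, then near-zero diastolic
#' flow. The in-vivo shape is emulated by a half-sine systolic lobe of
#' duration \code{fs * T}, a negative half-sine lobe of relative depth
#' \code{regurgitation} and duration \code{regurgitation_fraction * T}, and
#' zero flow elsewhere. The systolic fraction \code{fs} is solved so the
#' time-averaged |velocity| matches the case target, and the peak is scaled
#' to the case \code{U_max}; the resulting waveform reproduces the tabulated
#' peak and mean velocities exactly.
#'
#' @param case flow case, "FL", "FM" or "FH"; alternatively supply
#'   \code{U_max}/\code{U_mean} directly.
#' @param d tube diameter used to convert velocities to flow, m.
#' @param period cycle period T, s.
#' @param n number of samples over one period.
#' @param n_harmonics harmonics kept in the Fourier representation.
#' @param regurgitation depth of the valve-closure backflow dip, as a
#'   fraction of peak flow.
#' @param regurgitation_fraction duration of the dip, as a fraction of T.
#' @param U_max,U_mean velocity targets, m/s; defaults come from \code{case}.
#' @return a \code{\link{flow_waveform}}.
#' @export
flow_case_waveform <- function(case = c("FL", "FM", "FH"), d = 0.02,
                               period = 0.8, n = 400, n_harmonics = 12,
                               regurgitation = 0.08,
                               regurgitation_fraction = 0.1,
                               U_max = NULL, U_mean = NULL) {
  case <- match.arg(case)
  p <- .flow_case_table[[case]]
  if (is.null(U_max)) U_max <- p$U_max
  if (is.null(U_mean)) U_mean <- p$U_mean
  area <- pi * d^2 / 4
  tt <- (seq_len(n) - 1) * period / n
  shape <- function(fs) {
    s <- numeric(n)
    sys <- tt < fs * period
    s[sys] <- sin(pi * tt[sys] / (fs * period))
    dip <- tt >= fs * period & tt < (fs + regurgitation_fraction) * period
    s[dip] <- -regurgitation *
      sin(pi * (tt[dip] - fs * period) / (regurgitation_fraction * period))
    s
  }
  target <- U_mean / U_max
  f <- function(fs) mean(abs(shape(fs))) - target
  fs <- stats::uniroot(f, c(0.05, 1 - regurgitation_fraction - 0.01),
                       tol = 1e-10)$root
  q <- U_max * area * shape(fs)
  flow_waveform(tt, q, period, n_harmonics = n_harmonics)
}

#' Read / write flow waveforms as two-column CSV (time_s, flow_m3s)
#'
#' @param wf a \code{flow_waveform}.
#' @param path CSV file path.
#' @param period cycle period, s (reader only; defaults to the sample span
#'   extended by one step).
#' @return the waveform (reader) or \code{path} invisibly (writer).
#' @export
write_waveform_csv <- function(wf, path) {
  stopifnot(inherits(wf, "flow_waveform"))
  utils::write.csv(data.frame(time_s = wf$time, flow_m3s = wf$flow),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path, period = NULL) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "flow_m3s") %in% names(d)))
  if (is.null(period)) {
    dt <- stats::median(diff(d$time_s))
    period <- max(d$time_s) + dt
  }
  flow_waveform(d$time_s, d$flow_m3s, period)
}
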