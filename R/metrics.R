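#' Phase-ensemble statistics of vector fields
#'
#' Element-wise mean and (n-1 convention) standard deviation of the velocity
#' components over an ensemble of vector fields acquired at the same cardiac
#' phase across cycles. Only valid vectors contribute; the per-point
#' contributor count is recorded, and points with no valid contributor are
#' returned as NA (missing), never zero.
#'
#' @param fields list of \code{vector_field}s on identical grids.
#' @param use_ms average the m/s components (default) rather than px.
#' @return list with matrices \code{u_mean}, \code{v_mean}, \code{u_sd},
#'   \code{v_sd}, \code{n} and the shared grid coordinates.
#' @export
phase_average <- function(fields, use_ms = TRUE) {
  stopifnot(length(fields) >= 2)
  g1 <- fields[[1]]
  for (f in fields) {
    if (!identical(dim(f$u_px), dim(g1$u_px)) ||
        max(abs(f$x_px - g1$x_px)) > 1e-9) {
      stop("ensemble members must share an identical grid")
    }
  }
  comp <- function(f, which) {
    m <- if (use_ms) f[[paste0(which, "_ms")]] else f[[paste0(which, "_px")]]
    m[!f$valid & !f$replaced] <- NA
    m[!is.finite(m)] <- NA
    m
  }
  stat <- function(which) {
    arr <- simplify2array(lapply(fields, comp, which))
    n <- apply(arr, c(1, 2), function(v) sum(is.finite(v)))
    mean_ <- apply(arr, c(1, 2), function(v) {
      v <- v[is.finite(v)]; if (length(v)) mean(v) else NA_real_
    })
    sd_ <- apply(arr, c(1, 2), function(v) {
      v <- v[is.finite(v)]; if (length(v) >= 2) stats::sd(v) else NA_real_
    })
    list(mean = mean_, sd = sd_, n = n)
  }
  su <- stat("u"); sv <- stat("v")
  list(u_mean = su$mean, v_mean = sv$mean, u_sd = su$sd, v_sd = sv$sd,
       n = pmin(su$n, sv$n), x_px = g1$x_px, y_px = g1$y_px,
       x_mm = g1$x_mm, y_mm = g1$y_mm)
}

#' RMS of velocity fluctuations
#'
#' Combined in-plane fluctuation intensity
#' \eqn{u'_{rms} = \sqrt{\overline{u'^2_x} + \overline{u'^2_y}}}, where the
#' two terms are the squared phase-ensemble standard deviations of the
#' velocity components.
#'
#' @param ensemble list of \code{vector_field}s (passed to
#'   \code{\link{phase_average}}) or the result of \code{phase_average}.
#' @return matrix of u'_rms (same units as the averaged components).
#' @export
rms_fluctuations <- function(ensemble) {
  pa <- if (is.list(ensemble) && !is.null(ensemble$u_sd)) ensemble
        else phase_average(ensemble)
  sqrt(pa$u_sd^2 + pa$v_sd^2)
}

#' Out-of-plane vorticity of a vector field
#'
#' \eqn{\omega_z = \partial v/\partial x - \partial u/\partial y} on the
#' regular vector grid: central differences in the interior, one-sided at
#' the borders. Missing (masked) points propagate as NA.
#'
#' @param field a \code{vector_field} with m/s velocities, or a list with
#'   \code{u_ms}, \code{v_ms}, \code{x_mm}, \code{y_mm}.
#' @return matrix of vorticity, 1/s.
#' @export
vorticity <- function(field) {
  u <- field$u_ms; v <- field$v_ms
  if (is.null(u)) stop("field has no m/s velocities; supply scale and dt")
  if (nrow(u) < 3 || ncol(u) < 3) stop("grid smaller than 3x3")
  dx <- diff(field$x_mm[1:2]) / 1000    # m
  dy <- diff(field$y_mm[1:2]) / 1000
  ddx <- function(m) {
    nc <- ncol(m)
    cbind(m[, 2] - m[, 1],
          (m[, -(1:2), drop = FALSE] - m[, -((nc - 1):nc), drop = FALSE]) / 2,
          m[, nc] - m[, nc - 1]) / dx
  }
  ddy <- function(m) {
    nr <- nrow(m)
    rbind(m[2, ] - m[1, ],
          (m[-(1:2), , drop = FALSE] - m[-((nr - 1):nr), , drop = FALSE]) / 2,
          m[nr, ] - m[nr - 1, ]) / dy
  }
  ddx(v) - ddy(u)
}

#' Axisymmetric flow rate from a PIV velocity field
#'
#' Reconstructs the volumetric flow rate from the axial velocity component
#' by (i) averaging it along the axial direction over a band of stations,
#' (ii) folding the resulting diameter profile about the tube axis
#' (averaging the two halves), and (iii) integrating
#' \eqn{Q = 2\pi \int_0^R \bar u(r)\, r\, dr} by the trapezoidal rule with
#' the no-slip point (R, 0) appended.
#'
#' @param field a \code{vector_field} with mm coordinates and m/s
#'   velocities.
#' @param band axial band \code{c(x0, x1)} in the field's mm coordinates.
#' @param R tube radius, m.
#' @param axis_y_mm transverse coordinate of the tube axis, mm (same frame
#'   as \code{field$y_mm}).
#' @param use_valid_only drop invalid (non-replaced) vectors.
#' @return flow rate, m^3/s; attribute \code{profile} holds the folded
#'   (r_m, u_ms) profile used.
#' @export
flow_rate_from_profile <- function(field, band, R, axis_y_mm = 0,
                                   use_valid_only = TRUE) {
  stopifnot(inherits(field, "vector_field"), !is.null(field$u_ms))
  cols <- which(field$x_mm >= band[1] & field$x_mm <= band[2])
  if (!length(cols)) stop("axial band outside the field")
  u <- field$u_ms[, cols, drop = FALSE]
  if (use_valid_only) u[!(field$valid | field$replaced)[, cols]] <- NA
  ubar <- rowMeans(u, na.rm = TRUE)
  r_mm <- abs(field$y_mm - axis_y_mm)
  ok <- is.finite(ubar) & r_mm <= R * 1000
  if (!any(ok)) stop("axial band fully masked")
  # fold both halves into one radial profile
  r <- r_mm[ok] / 1000
  uu <- ubar[ok]
  o <- order(r)
  r <- r[o]; uu <- uu[o]
  agg <- stats::aggregate(uu, list(r = round(r, 9)), mean)
  r <- agg$r; uu <- agg$x
  if (r[length(r)] < R) { r <- c(r, R); uu <- c(uu, 0) }
  rf <- seq(0, R, length.out = 257)
  uf <- stats::approx(r, uu, rf, rule = 2)$y
  Q <- 2 * pi * sum(diff(rf) * (utils::head(uf * rf, -1) +
                                utils::tail(uf * rf, -1)) / 2)
  attr(Q, "profile") <- data.frame(r_m = r, u_ms = uu)
  Q
}

#' Difference map between two velocity fields
#'
#' Signed element-wise difference of velocity magnitude
#' \eqn{|v|_A - |v|_B} between two fields on the same grid (used to compare
#' illumination configurations); missing points propagate. The maximum
#' absolute difference over jointly valid points is attached.
#'
#' @param fieldA,fieldB \code{vector_field}s on identical grids, with m/s
#'   velocities.
#' @return matrix of signed magnitude differences, m/s, with attribute
#'   \code{max_abs}.
#' @export
config_difference <- function(fieldA, fieldB) {
  stopifnot(inherits(fieldA, "vector_field"), inherits(fieldB, "vector_field"))
  if (!identical(dim(fieldA$u_px), dim(fieldB$u_px)) ||
      max(abs(fieldA$x_px - fieldB$x_px)) > 1e-9) {
    stop("fields are on different grids")
  }
  # only measured vectors are compared: replaced values are neighborhood
  # interpolations, not measurements
  magn <- function(f) {
    m <- sqrt(f$u_ms^2 + f$v_ms^2)
    m[!f$valid] <- NA
    m
  }
  d <- magn(fieldA) - magn(fieldB)
  attr(d, "max_abs") <- max(abs(d[is.finite(d)]))
  d
}

#' Inlet/outlet flow balance of a sensor log
#'
#' Phase-averaged difference \eqn{\Delta Q(t) = Q_{in} - \sum Q_{out}} over
#' the cycle, with optional low-pass filtering and flowmeter-delay
#' compensation of the outlet channels before differencing.
#'
#' @param log a \code{sensor_log}.
#' @param lowpass_hz optional low-pass cutoff, Hz (2nd-order Butterworth,
#'   zero-phase).
#' @param delay_comp_s shift applied to the outlet channels before
#'   differencing, s (0 if the logged channels share one delay already).
#' @return data.frame with \code{time_s} (phase), \code{dq_mean},
#'   \code{dq_sd} (m^3/s).
#' @export
flow_balance <- function(log, lowpass_hz = NULL, delay_comp_s = 0) {
  stopifnot(inherits(log, "sensor_log"))
  d <- log$data
  qin <- d$q_in_m3s
  qout_cols <- grep("^q_out", names(d), value = TRUE)
  qout <- rowSums(d[, qout_cols, drop = FALSE])
  if (!is.null(lowpass_hz)) {
    bf <- signal::butter(2, lowpass_hz / (log$fs / 2))
    qin <- as.numeric(signal::filtfilt(bf, qin))
    qout <- as.numeric(signal::filtfilt(bf, qout))
  }
  if (delay_comp_s != 0) {
    nd <- as.integer(round(delay_comp_s * log$fs))
    qout <- qout[pmin(pmax(seq_along(qout) + nd, 1L), length(qout))]
  }
  dq <- qin - qout
  n <- length(dq)
  spc <- as.integer(round(log$period * log$fs))
  first_cycle <- ceiling(log$n_cycles / 2)
  sel <- d$time_s >= first_cycle * log$period - 1e-12
  phase_idx <- ((seq_len(n) - 1) %% spc) + 1L
  sp <- split(dq[sel], phase_idx[sel])
  data.frame(time_s = (seq_len(spc) - 1) / log$fs,
             dq_mean = vapply(sp, mean, 0),
             dq_sd = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else 0, 0))
}

#' Pressure-strain elastic modulus
#'
#' Distensibility measure \eqn{E_p = \Delta P / (\Delta D / D)}: the
#' pressure excursion divided by the relative diameter change it produces.
#' Inverse of the compliant-segment strain law.
#'
#' @param dP pressure excursion, Pa.
#' @param D reference diameter (same units as \code{dD}).
#' @param dD diameter change.
#' @return Ep, N/m^2.
#' @export
pressure_strain_modulus <- function(dP, D, dD) {
  strain <- dD / D
  if (any(strain <= 0)) stop("zero or negative strain")
  dP / strain
}

#' Convert a flow rate between m^3/s and L/min
#' @param q flow rate, m^3/s.
#' @return flow rate, L/min.
#' @export
m3s_to_lmin <- function(q) q * 6e4
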