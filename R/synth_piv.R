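#' Camera model
#'
#' Geometry and radiometry of the acquisition camera: a 1920 x 1200 sensor
#' recording 12-bit grayscale (stored in a 16-bit container), with a known
#' image scale and exposure/inter-frame timing.
#'
#' @param size sensor size, px, \code{c(width, height)}.
#' @param bit_depth bits per pixel (values clipped to \code{2^bit_depth - 1}).
#' @param scale image scale, px/mm.
#' @param exposure_us exposure time, microseconds; both LED pulses must fall
#'   within it, so it must be at least the active pulse separation.
#' @param min_interframe_us minimum inter-frame time, microseconds.
#' @return object of class \code{camera_model}.
#' @export
camera_model <- function(size = c(1920, 1200), bit_depth = 12, scale = 24.6,
                         exposure_us = 13000, min_interframe_us = 80) {
  stopifnot(all(size > 0), bit_depth > 0, scale > 0, exposure_us > 0)
  structure(list(size = as.integer(size), bit_depth = as.integer(bit_depth),
                 scale = scale, exposure_us = exposure_us,
                 min_interframe_us = min_interframe_us),
            class = "camera_model")
}

#' Pulsed-LED illumination configurations
#'
#' The four double-pulse settings evaluated on the rig, combining two pulse
#' widths (10 and 20 us) with two pulse separations (200 and 400 us). The
#' duty cycle tau/dt equals the ratio of the streaking distance during a
#' pulse to the inter-pulse particle displacement.
#'
#' @param label one of "C1".."C4", or NULL to build a custom config from
#'   \code{tau_us}/\code{dt_us}.
#' @param tau_us pulse width, us.
#' @param dt_us pulse separation, us.
#' @return object of class \code{illumination_config} with fields
#'   \code{label}, \code{tau_us}, \code{dt_us}, \code{duty_cycle}.
#' @export
illumination_config <- function(label = NULL, tau_us = NULL, dt_us = NULL) {
  presets <- list(C1 = c(10, 200), C2 = c(10, 400),
                  C3 = c(20, 200), C4 = c(20, 400))
  if (!is.null(label)) {
    label <- match.arg(label, names(presets))
    tau_us <- presets[[label]][1]; dt_us <- presets[[label]][2]
  } else {
    label <- sprintf("tau%g_dt%g", tau_us, dt_us)
  }
  stopifnot(tau_us > 0, tau_us < dt_us)
  structure(list(label = label, tau_us = tau_us, dt_us = dt_us,
                 duty_cycle = tau_us / dt_us),
            class = "illumination_config")
}

#' Womersley mid-plane velocity sampler
#'
#' Builds a velocity sampler for the mid-plane of a straight circular tube
#' carrying fully developed Womersley flow: axial velocity depends on the
#' transverse coordinate only (in the light-sheet plane through the axis the
#' transverse image coordinate is the radius), and the transverse component
#' is zero. The sampler signature is \code{f(x_mm, y_mm, t_s)} returning a
#' list with \code{u}, \code{v} in m/s.
#'
#' @param waveform a \code{\link{flow_waveform}}.
#' @param d tube inner diameter, m.
#' @param fluid a \code{\link{fluid_properties}}.
#' @param amplitude multiplicative factor on the waveform (used for
#'   cycle-to-cycle jitter).
#' @return sampler closure.
#' @export
womersley_sampler <- function(waveform, d = 0.02, fluid = fluid_properties(),
                              amplitude = 1) {
  force(waveform); force(d); force(fluid); force(amplitude)
  R_mm <- d / 2 * 1000
  n_grid <- 1024
  r_grid <- seq(0, d / 2, length.out = n_grid)
  function(x_mm, y_mm, t_s) {
    inside <- abs(y_mm) <= R_mm
    u <- numeric(length(y_mm))
    if (any(inside)) {
      r <- pmin(abs(y_mm[inside]), R_mm) / 1000
      if (length(r) > 2 * n_grid) {
        # dense query: evaluate on a radial grid and interpolate
        ug <- womersley_profile(waveform$harmonics, d, fluid,
                                waveform$period, r = r_grid, t = t_s)
        u[inside] <- amplitude * stats::approx(r_grid, ug, r)$y
      } else {
        u[inside] <- amplitude *
          womersley_profile(waveform$harmonics, d, fluid, waveform$period,
                            r = r, t = t_s)
      }
    }
    list(u = u, v = numeric(length(y_mm)))
  }
}

#' Seed tracer particles in a lumen mask
#'
#' Draws a Poisson number of hollow-glass-sphere tracers, uniformly over the
#' lumen area of the mask and uniformly across the light-sheet thickness.
#'
#' @param mask a \code{\link{lumen_mask}}.
#' @param density areal seeding density, particles per mm^2 of lumen.
#' @param sheet_thickness light-sheet thickness, mm.
#' @param seed RNG seed (same seed gives identical particle fields).
#' @return object of class \code{particle_field}: data.frame with
#'   \code{x_mm}, \code{y_mm} (in-plane, mask coordinates), \code{z_mm}
#'   (through-sheet), plus attributes \code{diameter_um},
#'   \code{sheet_thickness}.
#' @export
seed_particles <- function(mask, density = 7, sheet_thickness = 1.5,
                           seed = NULL) {
  stopifnot(inherits(mask, "lumen_mask"), density > 0, sheet_thickness > 0)
  idx <- which(mask$mask)
  if (length(idx) == 0) stop("empty lumen mask")
  if (!is.null(seed)) set.seed(seed)
  area_mm2 <- length(idx) / mask$scale^2
  n <- stats::rpois(1, density * area_mm2)
  pick <- sample(idx, n, replace = TRUE)
  row <- ((pick - 1) %% nrow(mask$mask)) + 1
  col <- ((pick - 1) %/% nrow(mask$mask)) + 1
  # jitter uniformly within the chosen pixel
  x <- mask$x_mm[col] + (stats::runif(n) - 0.5) / mask$scale
  y <- mask$y_mm[row] + (stats::runif(n) - 0.5) / mask$scale
  z <- (stats::runif(n) - 0.5) * sheet_thickness
  structure(data.frame(x_mm = x, y_mm = y, z_mm = z),
            class = c("particle_field", "data.frame"),
            diameter_um = 10, sheet_thickness = sheet_thickness,
            window = mask$window)
}

#' Advect particles through a velocity field
#'
#' Integrates particle positions over \code{dt_s} with classical 4th-order
#' Runge-Kutta in the (possibly time-varying) sampled velocity field.
#' Particles leaving the axial window are flagged \code{respawned} and
#' wrapped back to the inlet side (the field is axially invariant in the
#' straight-tube region, so wrapping preserves the flow statistics).
#'
#' @param particles a \code{particle_field}.
#' @param sampler velocity sampler \code{f(x_mm, y_mm, t_s) -> list(u, v)}
#'   in m/s.
#' @param dt_s integration time, s.
#' @param t0 start time within the cycle, s.
#' @param window axial window \code{c(x0, x1)} mm for respawning; defaults to
#'   the particle field's window.
#' @return displaced \code{particle_field} with logical column
#'   \code{respawned}.
#' @export
advect <- function(particles, sampler, dt_s, t0 = 0, window = NULL) {
  stopifnot(dt_s > 0)
  if (is.null(window)) window <- attr(particles, "window")
  x <- particles$x_mm; y <- particles$y_mm
  k <- function(xs, ys, ts) {
    v <- sampler(xs, ys, ts)
    if (any(!is.finite(v$u)) || any(!is.finite(v$v))) {
      stop("non-finite velocity from sampler")
    }
    list(u = v$u * 1000, v = v$v * 1000)   # m/s -> mm/s
  }
  k1 <- k(x, y, t0)
  k2 <- k(x + dt_s / 2 * k1$u, y + dt_s / 2 * k1$v, t0 + dt_s / 2)
  k3 <- k(x + dt_s / 2 * k2$u, y + dt_s / 2 * k2$v, t0 + dt_s / 2)
  k4 <- k(x + dt_s * k3$u, y + dt_s * k3$v, t0 + dt_s)
  xn <- x + dt_s / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u)
  yn <- y + dt_s / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v)
  respawned <- xn > window[2] | xn < window[1]
  width <- window[2] - window[1]
  if (any(respawned)) {
    xn[respawned] <- window[1] + (xn[respawned] - window[1]) %% width
  }
  out <- particles
  out$x_mm <- xn; out$y_mm <- yn
  out$respawned <- respawned
  out
}

# Accumulate Gaussian particle images onto a frame (rows = y, cols = x).
# pos_px: data.frame col/row in px (continuous, pixel centers at half-integer
# offsets already applied by the caller); amp: peak counts per particle.
.stamp_particles <- function(frame, col_px, row_px, amp, sigma_px) {
  k <- max(2L, ceiling(3 * sigma_px))
  nr <- nrow(frame); nc <- ncol(frame)
  ic <- floor(col_px); ir <- floor(row_px)
  for (dy in -k:k) {
    rr <- ir + dy
    ok_r <- rr >= 1 & rr <= nr
    if (!any(ok_r)) next
    for (dx in -k:k) {
      cc <- ic + dx
      ok <- ok_r & cc >= 1 & cc <= nc
      if (!any(ok)) next
      w <- amp[ok] * exp(-(((cc[ok] - 0.5) - col_px[ok])^2 +
                           ((rr[ok] - 0.5) - row_px[ok])^2) / (2 * sigma_px^2))
      idx <- rr[ok] + (cc[ok] - 1) * nr
      acc <- tapply(w, idx, sum)
      ii <- as.integer(names(acc))
      frame[ii] <- frame[ii] + as.numeric(acc)
    }
  }
  frame
}

#' Background model for synthetic frames
#'
#' Static background: a constant offset, a smooth large-scale gradient, and
#' an optional bright band hugging the wall contour that emulates the
#' wall-reflection artifact seen on the rig.
#'
#' @param offset constant background level, counts.
#' @param gradient peak-to-peak amplitude of a smooth diagonal gradient,
#'   counts.
#' @param wall_band amplitude of the wall-reflection band, counts.
#' @param wall_sigma_px Gaussian width of the band, px.
#' @param band_jitter_px per-pair transverse jitter of the reflection band
#'   position, px (standard deviation). The compliant wall moves over the
#'   cardiac cycle, so the glare band is not static between acquisitions and
#'   survives mean-background subtraction as a residual; the jitter emulates
#'   that. Within a pair (400 us) the wall is effectively frozen, so both
#'   frames share one draw.
#' @return object of class \code{background_model}.
#' @export
background_model <- function(offset = 100, gradient = 60, wall_band = 300,
                             wall_sigma_px = 3, band_jitter_px = 2) {
  structure(list(offset = offset, gradient = gradient, wall_band = wall_band,
                 wall_sigma_px = wall_sigma_px,
                 band_jitter_px = band_jitter_px),
            class = "background_model")
}

# returns the static part and the wall band separately so the band can be
# displaced per pair
.render_background <- function(mask, bg) {
  m <- mask$mask
  nr <- nrow(m); nc <- ncol(m)
  gx <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
  gy <- matrix(rep(seq_len(nr) / nr, nc), nr, nc)
  static <- bg$offset + bg$gradient * 0.5 * (gx + gy)
  band <- NULL
  if (bg$wall_band > 0) {
    edge <- m != rbind(m[-1, ], m[nr, ])          # wall boundary pixels
    band <- EBImage::gblur(edge * 1.0, sigma = bg$wall_sigma_px)
    if (max(band) > 0) band <- bg$wall_band * band / max(band)
  }
  list(static = static, band = band)
}

# vertical roll of an image by an integer number of rows (edge padded)
.roll_rows <- function(m, k) {
  if (k == 0) return(m)
  nr <- nrow(m)
  idx <- pmin(pmax(seq_len(nr) - k, 1L), nr)
  m[idx, , drop = FALSE]
}

#' Render one double-exposure image pair
#'
#' Renders two 12-bit frames of a seeded flow: diffraction-limited Gaussian
#' particle spots (e^-2 diameter ~2.6 px) streaked along the path traversed
#' during the LED pulse width, with the second pulse displaced by the flow
#' over the pulse separation. Particle brightness is weighted by a Gaussian
#' light-sheet intensity profile across the sheet depth. A static background
#' (offset, smooth gradient, wall-reflection band) and Poisson-Gaussian
#' sensor noise are added, and pixel values are clipped to the camera bit
#' depth.
#'
#' @param particles a \code{particle_field} (first-pulse positions).
#' @param mask the \code{\link{lumen_mask}} defining the imaged window (sets
#'   the frame size and the mm-to-px mapping).
#' @param camera a \code{\link{camera_model}}.
#' @param illum an \code{\link{illumination_config}}.
#' @param sampler velocity sampler (m/s) used for the inter-pulse
#'   displacement and the intra-pulse streak.
#' @param t0 time within the cycle of the first pulse, s.
#' @param background a \code{\link{background_model}}.
#' @param peak_counts peak particle-image intensity for a 20 us reference
#'   pulse, counts (12-bit scale); the delivered pulse energy, and hence the
#'   integrated spot intensity, scales linearly with the pulse width.
#' @param spot_sigma_px Gaussian spot sigma, px.
#' @param read_noise_sd Gaussian read noise, counts; set 0 (with
#'   \code{shot_noise = FALSE}) for noise-free frames.
#' @param shot_noise add Poisson-like shot noise (Gaussian approximation with
#'   variance equal to the signal).
#' @param n_streak sub-pulse samples used to draw the motion streak.
#' @param seed RNG seed for the noise.
#' @return list of class \code{image_pair}: \code{a}, \code{b} (matrices,
#'   rows = y, cols = x, counts), \code{t0}, \code{illum}, \code{saturation}
#'   (fraction of saturated pixels; a warning flag \code{saturated} is set
#'   above 50\%).
#' @export
render_pair <- function(particles, mask, camera, illum, sampler, t0 = 0,
                        background = background_model(),
                        peak_counts = 900, spot_sigma_px = 0.65,
                        read_noise_sd = 4, shot_noise = TRUE,
                        n_streak = 3, seed = NULL) {
  stopifnot(inherits(mask, "lumen_mask"), inherits(camera, "camera_model"),
            inherits(illum, "illumination_config"))
  if (illum$dt_us > camera$exposure_us) {
    stop("pulse separation exceeds the camera exposure window")
  }
  if (!is.null(seed)) set.seed(seed)
  nr <- nrow(mask$mask); nc <- ncol(mask$mask)
  scale <- mask$scale
  sheet <- attr(particles, "sheet_thickness")
  # sheet-depth intensity weighting (Gaussian sheet, sigma = thickness/4);
  # pulse energy proportional to pulse width (20 us reference)
  amp <- peak_counts * (illum$tau_us / 20) *
    exp(-particles$z_mm^2 / (2 * (sheet / 4)^2))

  to_px <- function(p) {
    list(col = (p$x_mm - mask$window[1]) * scale,
         row = p$y_mm * scale + nr / 2)
  }
  render_pulse <- function(p_start, t_pulse) {
    fr <- matrix(0, nr, nc)
    p <- p_start
    tau_s <- illum$tau_us * 1e-6
    for (s in seq_len(n_streak)) {
      px <- to_px(p)
      fr <- .stamp_particles(fr, px$col, px$row, amp / n_streak, spot_sigma_px)
      if (s < n_streak) {
        p <- advect(p, sampler, tau_s / (n_streak - 1),
                    t_pulse + (s - 1) * tau_s / (n_streak - 1))
      }
    }
    fr
  }
  bgp <- .render_background(mask, background)
  bg <- bgp$static
  if (!is.null(bgp$band)) {
    dy <- if (background$band_jitter_px > 0) {
      as.integer(round(stats::rnorm(1, 0, background$band_jitter_px)))
    } else 0L
    bg <- bg + .roll_rows(bgp$band, dy)
  }
  pA <- particles
  pB <- advect(particles, sampler, illum$dt_us * 1e-6, t0)
  a <- render_pulse(pA, t0) + bg
  b <- render_pulse(pB, t0 + illum$dt_us * 1e-6) + bg
  add_noise <- function(fr) {
    if (shot_noise) fr <- fr + stats::rnorm(length(fr), 0, sqrt(pmax(fr, 0)))
    if (read_noise_sd > 0) fr <- fr + stats::rnorm(length(fr), 0, read_noise_sd)
    fr
  }
  a <- add_noise(a); b <- add_noise(b)
  vmax <- 2^camera$bit_depth - 1
  sat <- mean(c(a, b) >= vmax)
  a <- matrix(pmin(pmax(round(a), 0), vmax), nr, nc)
  b <- matrix(pmin(pmax(round(b), 0), vmax), nr, nc)
  out <- list(a = a, b = b, t0 = t0, illum = illum, saturation = sat,
              saturated = sat > 0.5)
  if (out$saturated) warning(sprintf("saturation fraction %.1f%%", 100 * sat))
  class(out) <- "image_pair"
  out
}

#' Ground-truth displacement on a PIV grid
#'
#' Integrates the velocity sampler over the pulse separation at each PIV grid
#' point (same RK4 integrator as particle advection) and returns the
#' displacement in pixels on the image grid.
#'
#' @param grid list with \code{x_px}, \code{y_px} (vector of window-center
#'   coordinates, px) as produced by \code{\link{piv_grid}}.
#' @param mask the \code{lumen_mask} (mm mapping).
#' @param sampler velocity sampler, m/s.
#' @param dt_us pulse separation, us.
#' @param t0 time of the first pulse, s.
#' @return list with matrices \code{u_px}, \code{v_px} (rows = y grid, cols =
#'   x grid).
#' @export
ground_truth_displacement <- function(grid, mask, sampler, dt_us, t0 = 0) {
  nr <- nrow(mask$mask)
  xg <- rep(grid$x_px, each = length(grid$y_px))
  yg <- rep(grid$y_px, length(grid$x_px))
  p <- structure(
    data.frame(x_mm = mask$window[1] + xg / mask$scale,
               y_mm = (yg - nr / 2) / mask$scale,
               z_mm = 0),
    class = c("particle_field", "data.frame"),
    sheet_thickness = 1, window = c(-1e9, 1e9))
  q <- advect(p, sampler, dt_us * 1e-6, t0)
  u <- (q$x_mm - p$x_mm) * mask$scale
  v <- (q$y_mm - p$y_mm) * mask$scale
  list(u_px = matrix(u, length(grid$y_px), length(grid$x_px)),
       v_px = matrix(v, length(grid$y_px), length(grid$x_px)))
}

#' Generate a synthetic phase-locked image-pair dataset
#'
#' Renders the full acquisition of one flow case: \code{phases} image pairs
#' per cardiac cycle (phase-locked across cycles) for \code{n_cycles} cycles,
#' under one illumination configuration, with per-pair ground-truth
#' displacement stored on the final PIV grid. Optional cycle-to-cycle
#' amplitude jitter emulates physiological flow fluctuations.
#'
#' @param waveform a \code{\link{flow_waveform}} (the reference inlet flow).
#' @param mask imaging window \code{\link{lumen_mask}} (straight-tube region
#'   for Womersley flow).
#' @param camera a \code{\link{camera_model}}.
#' @param illum an \code{\link{illumination_config}}.
#' @param d tube diameter, m.
#' @param fluid a \code{\link{fluid_properties}}.
#' @param n_cycles number of cycles.
#' @param phases image pairs per cycle.
#' @param pair_interval_s interval between successive pairs, s; defaults to
#'   \code{period / phases}.
#' @param jitter cycle-to-cycle amplitude jitter (relative sd; 0 disables).
#' @param density seeding density, particles/mm^2.
#' @param final_window final PIV window size, px (sets the ground-truth
#'   grid).
#' @param overlap PIV window overlap (ground-truth grid).
#' @param seed master RNG seed.
#' @param ... further arguments passed to \code{\link{render_pair}}.
#' @return object of class \code{image_pair_sequence}: list with
#'   \code{pairs} (list of \code{image_pair}, cycle-major order), \code{gt}
#'   (list of ground-truth displacement lists, aligned with \code{pairs}),
#'   \code{phase_t} (times within cycle), \code{cycle}, \code{phase} index
#'   vectors, \code{grid}, \code{mask}, \code{camera}, \code{illum},
#'   \code{seed}.
#' @export
generate_dataset <- function(waveform, mask, camera, illum, d = 0.02,
                             fluid = fluid_properties(), n_cycles = 1,
                             phases = 25, pair_interval_s = NULL,
                             jitter = 0, density = 7,
                             final_window = 32, overlap = 0.5,
                             seed = 1, ...) {
  stopifnot(inherits(waveform, "flow_waveform"))
  if (is.null(pair_interval_s)) pair_interval_s <- waveform$period / phases
  if (pair_interval_s * 1e6 < camera$min_interframe_us) {
    stop("pair interval shorter than the camera minimum inter-frame time")
  }
  grid <- piv_grid(dim(mask$mask), final_window, overlap)
  phase_t <- (seq_len(phases) - 1) * pair_interval_s
  set.seed(seed)
  amps <- if (jitter > 0) 1 + stats::rnorm(n_cycles, 0, jitter) else rep(1, n_cycles)
  pair_seeds <- matrix(sample.int(.Machine$integer.max - 1, n_cycles * phases),
                       n_cycles, phases)
  pairs <- vector("list", n_cycles * phases)
  gt <- vector("list", n_cycles * phases)
  cyc <- integer(n_cycles * phases); ph <- integer(n_cycles * phases)
  i <- 0
  for (ci in seq_len(n_cycles)) {
    sampler <- womersley_sampler(waveform, d, fluid, amplitude = amps[ci])
    for (pi in seq_len(phases)) {
      i <- i + 1
      parts <- seed_particles(mask, density = density,
                              seed = pair_seeds[ci, pi])
      pairs[[i]] <- render_pair(parts, mask, camera, illum, sampler,
                                t0 = phase_t[pi], seed = pair_seeds[ci, pi], ...)
      gt[[i]] <- ground_truth_displacement(grid, mask, sampler,
                                           illum$dt_us, phase_t[pi])
      cyc[i] <- ci; ph[i] <- pi
    }
  }
  structure(list(pairs = pairs, gt = gt, phase_t = phase_t, cycle = cyc,
                 phase = ph, grid = grid, mask = mask, camera = camera,
                 illum = illum, seed = seed, waveform = waveform, d = d,
                 fluid = fluid),
            class = "image_pair_sequence")
}

#' Write an image pair as 16-bit grayscale TIFF
#'
#' File names encode cycle, phase and pulse, e.g. \code{c012_p07_a.tif}.
#'
#' @param pair an \code{image_pair}.
#' @param dir output directory.
#' @param cycle,phase indices used in the file name.
#' @param bit_depth source bit depth (for scaling into the 16-bit container).
#' @return character vector of the two file paths, invisibly.
#' @export
write_pair_tiff <- function(pair, dir, cycle = 1, phase = 1, bit_depth = 12) {
  stopifnot(inherits(pair, "image_pair"))
  vmax <- 2^bit_depth - 1
  fa <- file.path(dir, sprintf("c%03d_p%02d_a.tif", cycle, phase))
  fb <- file.path(dir, sprintf("c%03d_p%02d_b.tif", cycle, phase))
  tiff::writeTIFF(pair$a / vmax, fa, bits.per.sample = 16)
  tiff::writeTIFF(pair$b / vmax, fb, bits.per.sample = 16)
  invisible(c(fa, fb))
}

#' Read a 16-bit TIFF frame back to counts
#' @param path TIFF path.
#' @param bit_depth stored source bit depth.
#' @return numeric matrix of counts.
#' @export
read_frame_tiff <- function(path, bit_depth = 12) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * (2^bit_depth - 1)
}
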