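test_that("particle seeding is Poisson in count, reproducible and confined
           to the lumen", {
  m <- small_tube_mask(scale = 10, width_px = 128, height_px = 260)
  area <- sum(m$mask) / m$scale^2
  lambda <- 10 * area
  counts <- vapply(1:40, function(s) nrow(seed_particles(m, 10, seed = s)), 0)
  # all counts inside the 99.99% Poisson envelope
  expect_true(all(counts > qpois(5e-5, lambda) &
                  counts < qpois(1 - 5e-5, lambda)))
  p1 <- seed_particles(m, 10, seed = 3)
  p2 <- seed_particles(m, 10, seed = 3)
  expect_identical(p1, p2)
  # every particle inside the analytic lumen
  r_at_x <- bulge_radius(aaa_geometry(), p1$x_mm)
  expect_true(all(abs(p1$y_mm) <= r_at_x + 1 / m$scale))
  expect_true(all(abs(p1$z_mm) <= attr(p1, "sheet_thickness") / 2))
  empty <- m; empty$mask[] <- FALSE
  expect_error(seed_particles(empty, 10), "empty")
})

test_that("advection is exact for uniform fields and preserves radii under
           solid-body rotation", {
  m <- small_tube_mask(scale = 10, width_px = 128, height_px = 260)
  p <- seed_particles(m, 5, seed = 1)
  q <- advect(p, uniform_sampler(0.5, -0.2), dt_s = 1e-3,
              window = c(-1e6, 1e6))
  expect_equal(q$x_mm - p$x_mm, rep(0.5, nrow(p)), tolerance = 1e-12)
  expect_equal(q$y_mm - p$y_mm, rep(-0.2, nrow(p)), tolerance = 1e-12)
  q0 <- advect(p, uniform_sampler(0, 0), dt_s = 1e-3)
  expect_equal(q0$x_mm, p$x_mm)
  # solid-body rotation: radius invariant to 1e-6 relative
  ctr <- c(mean(range(p$x_mm)), 0)
  rot <- rotation_sampler(2 * pi * 5, ctr[1], ctr[2])
  q2 <- advect(p, rot, dt_s = 1e-3, window = c(-1e6, 1e6))
  r0 <- sqrt((p$x_mm - ctr[1])^2 + p$y_mm^2)
  r1 <- sqrt((q2$x_mm - ctr[1])^2 + q2$y_mm^2)
  expect_lt(max(abs(r1 - r0) / pmax(r0, 1e-9)), 1e-6)
  # exiting particles are flagged and wrapped to the inlet
  fast <- advect(p, uniform_sampler(20), dt_s = 1e-3)
  expect_true(any(fast$respawned))
  expect_true(all(fast$x_mm >= attr(p, "window")[1] - 1e-9 &
                  fast$x_mm <= attr(p, "window")[2] + 1e-9))
  expect_error(advect(p, function(x, y, t) list(u = x * NaN, v = x * 0),
                      dt_s = 1e-3), "non-finite")
})

test_that("rendered pairs are identical for zero velocity without noise,
           and pulse energy scales with pulse width", {
  m <- small_tube_mask(scale = 10, width_px = 128, height_px = 260)
  cam <- camera_model(scale = 10)
  p <- seed_particles(m, 5, seed = 2)
  still <- render_pair(p, m, cam, illumination_config("C4"),
                       uniform_sampler(0, 0), read_noise_sd = 0,
                       shot_noise = FALSE, seed = 2,
                       background = background_model(band_jitter_px = 0))
  expect_identical(still$a, still$b)
  expect_true(all(still$a >= 0 & still$a <= 4095))
  # doubling tau doubles the integrated particle energy (C2 -> C4)
  bg0 <- background_model(offset = 0, gradient = 0, wall_band = 0)
  e <- sapply(c("C2", "C4"), function(lab) {
    pr <- render_pair(p, m, cam, illumination_config(lab),
                      uniform_sampler(0, 0), read_noise_sd = 0,
                      shot_noise = FALSE, background = bg0)
    sum(pr$a)
  })
  expect_equal(e[["C4"]] / e[["C2"]], 2, tolerance = 1e-2)
  # pulse separation longer than the exposure is rejected
  cam_short <- camera_model(scale = 10, exposure_us = 300)
  expect_error(render_pair(p, m, cam_short, illumination_config("C4"),
                           uniform_sampler(0, 0)), "exposure")
})

test_that("the four illumination configurations share first-pulse particle
           positions for a fixed seed and differ only in streak and
           displacement", {
  m <- small_tube_mask(scale = 10, width_px = 128, height_px = 260)
  cam <- camera_model(scale = 10)
  bg0 <- background_model(offset = 0, gradient = 0, wall_band = 0)
  frames <- lapply(c("C1", "C2", "C3", "C4"), function(lab) {
    p <- seed_particles(m, 5, seed = 9)
    render_pair(p, m, cam, illumination_config(lab), uniform_sampler(0.3),
                read_noise_sd = 0, shot_noise = FALSE, background = bg0,
                seed = 9)
  })
  # same pulse width -> identical frame A (same energy, same positions)
  expect_identical(frames[[1]]$a, frames[[2]]$a)   # C1 vs C2 (10 us)
  expect_identical(frames[[3]]$a, frames[[4]]$a)   # C3 vs C4 (20 us)
  # same separation -> same inter-pulse displacement: frame B of C2 equals
  # C4's up to the 2x energy factor and the sub-pixel streak-centroid
  # shift (0.015 px here, worth a few % of the peak on spot flanks)
  expect_lt(max(abs(frames[[2]]$b * 2 - frames[[4]]$b)), 40)
})

test_that("ground-truth displacement matches a finer re-integration of the
           sampler to 1e-3 px", {
  m <- small_tube_mask(scale = 24.6, width_px = 128, height_px = 560)
  wf <- flow_case_waveform("FH")
  smp <- womersley_sampler(wf, 0.02, fluid_properties())
  g <- piv_grid(dim(m$mask), 32, 0.5)
  gt <- ground_truth_displacement(g, m, smp, dt_us = 400, t0 = 0.12)
  # oracle: compose 8 short RK4 sub-steps through the same sampler
  nr <- nrow(m$mask)
  xg <- rep(g$x_px, each = length(g$y_px))
  yg <- rep(g$y_px, length(g$x_px))
  x <- m$window[1] + xg / m$scale
  y <- (yg - nr / 2) / m$scale
  p <- structure(data.frame(x_mm = x, y_mm = y, z_mm = 0),
                 class = c("particle_field", "data.frame"),
                 sheet_thickness = 1, window = c(-1e9, 1e9))
  t0 <- 0.12
  for (s in 1:8) {
    p <- advect(p, smp, 400e-6 / 8, t0)
    t0 <- t0 + 400e-6 / 8
  }
  u_fine <- (p$x_mm - x) * m$scale
  expect_lt(max(abs(as.vector(gt$u_px) - u_fine)), 1e-3)
})

test_that("dataset generation is phase-locked, jitter-free by default and
           validates the pair interval", {
  m <- small_tube_mask(scale = 10, width_px = 128, height_px = 260)
  cam <- camera_model(scale = 10)
  wf <- flow_case_waveform("FL", n = 100)
  ds <- generate_dataset(wf, m, cam, illumination_config("C4"),
                         n_cycles = 2, phases = 3, density = 4, seed = 5)
  expect_length(ds$pairs, 6)
  expect_equal(ds$phase, rep(1:3, 2))
  # no jitter: ground truth identical across cycles at fixed phase
  expect_equal(ds$gt[[1]]$u_px, ds$gt[[4]]$u_px, tolerance = 1e-12)
  ds2 <- generate_dataset(wf, m, cam, illumination_config("C4"),
                          n_cycles = 2, phases = 3, density = 4, seed = 5,
                          jitter = 0.05)
  expect_gt(max(abs(ds2$gt[[1]]$u_px - ds2$gt[[4]]$u_px)), 0)
  expect_error(generate_dataset(wf, m, cam, illumination_config("C4"),
                                phases = 3, pair_interval_s = 5e-5),
               "inter-frame")
})

test_that("image pairs round-trip through 16-bit TIFF", {
  m <- small_tube_mask(scale = 10, width_px = 128, height_px = 260)
  cam <- camera_model(scale = 10)
  p <- seed_particles(m, 5, seed = 2)
  pr <- render_pair(p, m, cam, illumination_config("C4"),
                    uniform_sampler(0.1), seed = 2)
  td <- tempfile(); dir.create(td)
  paths <- write_pair_tiff(pr, td, cycle = 12, phase = 7)
  expect_true(all(file.exists(paths)))
  expect_match(basename(paths[1]), "c012_p07_a")
  back <- read_frame_tiff(paths[1])
  # 12-bit counts in a 16-bit container: within one 16-bit quantization step
  expect_lt(max(abs(back - pr$a)), 4095 / 65535 * 1.01)
  unlink(td, recursive = TRUE)
})

test_that("rendered image statistics match the configured background level
           and seeding density within 5%", {
  m <- small_tube_mask(scale = 10, width_px = 192, height_px = 260)
  cam <- camera_model(scale = 10)
  bg <- background_model(offset = 120, gradient = 0, wall_band = 0)
  dens <- 8
  set.seed(20)
  tot <- 0; n_rep <- 6
  for (i in 1:n_rep) {
    p <- seed_particles(m, dens, sheet_thickness = 1.5, seed = 20 + i)
    pr <- render_pair(p, m, cam, illumination_config("C4"),
                      uniform_sampler(0, 0), background = bg,
                      read_noise_sd = 0, shot_noise = FALSE, seed = 20 + i)
    # background level: the lower quantiles of the lumen histogram sit at
    # the offset (spot cores and wings only lift the upper half)
    expect_equal(unname(quantile(pr$a[m$mask], 0.2)), 120, tolerance = 0.05)
    tot <- tot + sum(pr$a - 120)
  }
  # integrated particle signal -> effective particle count; oracle: expected
  # per-particle energy = peak * 2*pi*sigma^2 * mean sheet weight
  sheet_w <- integrate(function(z) exp(-z^2 / (2 * (1.5 / 4)^2)) / 1.5,
                       -0.75, 0.75)$value
  per_particle <- 900 * 2 * pi * 0.65^2 * sheet_w
  n_est <- tot / n_rep / per_particle
  n_exp <- dens * sum(m$mask) / m$scale^2
  expect_equal(n_est, n_exp, tolerance = 0.05)
})

test_that("gross saturation is flagged with a warning in the metadata", {
  m <- small_tube_mask(scale = 10, width_px = 128, height_px = 260)
  cam <- camera_model(scale = 10)
  p <- seed_particles(m, 5, seed = 1)
  expect_warning(
    pr <- render_pair(p, m, cam, illumination_config("C4"),
                      uniform_sampler(0, 0),
                      background = background_model(offset = 5000),
                      seed = 1),
    "saturation")
  expect_true(pr$saturated)
  expect_gt(pr$saturation, 0.5)
})
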