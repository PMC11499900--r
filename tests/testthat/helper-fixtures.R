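# Shared fixtures, all built in code.

# small imaging window over the straight parent-tube region of the default
# idealized geometry, sized for fast PIV tests (>= 128 px in both dims)
small_tube_mask <- function(scale = 24.6, width_px = 256, height_px = 560) {
  lumen_mask(aaa_geometry(), c(-120, -120 + width_px / scale), scale,
             c(width_px, height_px))
}

# random-particle frame pair with a rigid uniform shift; particles are
# seeded beyond the borders so shifted content exists everywhere
make_shift_pair <- function(shift_u, shift_v = 0, nr = 256, nc = 256,
                            n = 700, seed = 1) {
  set.seed(seed)
  margin <- max(abs(c(shift_u, shift_v))) + 8
  cx <- runif(n, -margin, nc + margin)
  cy <- runif(n, -margin, nr + margin)
  render <- function(cx, cy) {
    fr <- matrix(0, nr, nc)
    for (k in -2:2) for (j in -2:2) {
      rr <- round(cy) + k; cc <- round(cx) + j
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      w <- 900 * exp(-(((cc - 0.5) - cx)^2 + ((rr - 0.5) - cy)^2) / (2 * 0.8^2))
      idx <- rr[ok] + (cc[ok] - 1) * nr
      acc <- tapply(w[ok], idx, sum)
      fr[as.integer(names(acc))] <- fr[as.integer(names(acc))] + acc
    }
    fr
  }
  list(a = render(cx, cy), b = render(cx + shift_u, cy + shift_v))
}

# constant-velocity sampler, u/v in m/s
uniform_sampler <- function(u, v = 0) {
  function(x_mm, y_mm, t_s) {
    list(u = rep(u, length(x_mm)), v = rep(v, length(x_mm)))
  }
}

# solid-body rotation about (x0, y0), angular rate omega (rad/s)
rotation_sampler <- function(omega, x0 = 0, y0 = 0) {
  function(x_mm, y_mm, t_s) {
    # velocities in m/s from mm coordinates
    list(u = -omega * (y_mm - y0) / 1000, v = omega * (x_mm - x0) / 1000)
  }
}

# hand-built vector field on a regular grid for metric tests
make_vector_field <- function(u_ms, v_ms = u_ms * 0, dx_mm = 1,
                              scale = 1, dt_s = 1e-3) {
  ny <- nrow(u_ms); nx <- ncol(u_ms)
  fac <- scale * dt_s * 1000
  f <- structure(list(
    x_px = seq_len(nx) * dx_mm * scale, y_px = seq_len(ny) * dx_mm * scale,
    u_px = u_ms * fac, v_px = v_ms * fac,
    snr = matrix(10, ny, nx), valid = matrix(TRUE, ny, nx),
    replaced = matrix(FALSE, ny, nx), mask_frac = matrix(0, ny, nx),
    window = 32, step = 16, scale = scale, dt_s = dt_s,
    origin_mm = c(0, 0)), class = "vector_field")
  aaapiv:::.finalize_field(f)
}
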