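#' Preprocessing configuration
#'
#' Parameters of the fixed image-conditioning pipeline applied before
#' correlation: mean-background subtraction, percentile intensity rescaling,
#' contrast-limited adaptive histogram equalization (CLAHE) and Gaussian
#' smoothing.
#'
#' @param low,high rescale percentiles (default 20 and 99.5).
#' @param clahe_nx CLAHE tile grid (nx by nx).
#' @param clahe_limit CLAHE contrast limit (EBImage convention).
#' @param sigma Gaussian blur sigma, px.
#' @return object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(low = 20, high = 99.5, clahe_nx = 8,
                              clahe_limit = 2, sigma = 1) {
  stopifnot(low >= 0, low < high, high <= 100, clahe_nx >= 1, sigma >= 0)
  structure(list(low = low, high = high, clahe_nx = clahe_nx,
                 clahe_limit = clahe_limit, sigma = sigma),
            class = "preprocess_config")
}

.apply_clahe <- function(m, config) {
  # CLAHE requires dimensions divisible by the tile grid: pad by edge
  # replication, equalize, crop back
  nr <- nrow(m); nc <- ncol(m)
  mult <- 2 * config$clahe_nx
  pr <- (mult - nr %% mult) %% mult
  pc <- (mult - nc %% mult) %% mult
  mp <- m
  if (pr > 0) mp <- rbind(mp, mp[rep(nr, pr), , drop = FALSE])
  if (pc > 0) mp <- cbind(mp, mp[, rep(nc, pc), drop = FALSE])
  img <- EBImage::Image(t(mp))
  out <- EBImage::clahe(img, nx = config$clahe_nx, ny = config$clahe_nx,
                        limit = config$clahe_limit, keep.range = TRUE)
  t(EBImage::imageData(out))[seq_len(nr), seq_len(nc), drop = FALSE]
}

#' Preprocess a stack of frames
#'
#' Fixed pipeline: the background is the pixel-wise mean over the stack and
#' is subtracted from every frame (negatives clipped at zero); each frame is
#' then rescaled so its \code{low}/\code{high} intensity percentiles map to
#' [0, 1] (clipped), equalized with CLAHE, and Gaussian-blurred.
#'
#' @param stack list of frames (numeric matrices of equal size, counts).
#' @param config a \code{\link{preprocess_config}}.
#' @param background optional precomputed background image (counts), e.g.
#'   the average over a longer acquisition than \code{stack}; by default the
#'   pixel-wise mean of \code{stack}.
#' @return list with \code{frames} (filtered, in [0, 1]) and
#'   \code{background} (counts).
#' @export
preprocess <- function(stack, config = preprocess_config(),
                       background = NULL) {
  stopifnot(is.list(stack), length(stack) >= 2 || !is.null(background))
  bg <- if (is.null(background)) Reduce(`+`, stack) / length(stack)
        else background
  frames <- lapply(stack, function(fr) {
    x <- pmax(fr - bg, 0)
    qs <- stats::quantile(x, c(config$low, config$high) / 100, names = FALSE)
    if (qs[2] <= qs[1]) {
      stop("degenerate intensity range after background subtraction; ",
           "cannot rescale a constant frame")
    }
    x <- pmin(pmax((x - qs[1]) / (qs[2] - qs[1]), 0), 1)
    x <- .apply_clahe(x, config)
    if (config$sigma > 0) {
      x <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(x)),
                                               sigma = config$sigma)))
    }
    x
  })
  list(frames = frames, background = bg)
}

# --- wall segmentation -------------------------------------------------------

#' Initial wall contour from a lumen mask
#'
#' Per-column first/last lumen row, usable as the manual initialization of
#' the active-contour segmentation (optionally perturbed).
#'
#' @param mask logical matrix (TRUE inside lumen) or a \code{lumen_mask}.
#' @param jitter_px uniform perturbation amplitude, px.
#' @param seed RNG seed for the perturbation.
#' @return list with \code{upper} and \code{lower} row coordinates per
#'   column (px).
#' @export
contour_from_mask <- function(mask, jitter_px = 0, seed = NULL) {
  if (inherits(mask, "lumen_mask")) mask <- mask$mask
  nc <- ncol(mask)
  upper <- lower <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    r <- which(mask[, j])
    if (length(r)) { upper[j] <- min(r) - 0.5; lower[j] <- max(r) + 0.5 }
  }
  upper <- stats::approx(seq_len(nc), upper, seq_len(nc), rule = 2)$y
  lower <- stats::approx(seq_len(nc), lower, seq_len(nc), rule = 2)$y
  if (jitter_px > 0) {
    if (!is.null(seed)) set.seed(seed)
    upper <- upper + stats::runif(nc, -jitter_px, jitter_px)
    lower <- lower + stats::runif(nc, -jitter_px, jitter_px)
  }
  list(upper = upper, lower = lower)
}

# sample a matrix at (row = y, col = j) positions, linear in y
.sample_rows <- function(m, y, cols) {
  nr <- nrow(m)
  y <- pmin(pmax(y, 1), nr - 1e-9)
  i0 <- pmin(floor(y), nr - 1)
  w <- y - i0
  m[cbind(i0, cols)] * (1 - w) + m[cbind(i0 + 1, cols)] * w
}

#' Active-contour segmentation of the phantom wall
#'
#' Segments the upper and lower wall edge of the (roughly horizontal) lumen
#' in a preprocessed frame with two open snakes, one per edge: each contour
#' is a row coordinate per image column that climbs the vertical intensity
#' gradient magnitude under a second-difference smoothness penalty
#' (semi-implicit Euler iteration). The transverse lumen extent
#' \code{Y(x) = lower - upper} is returned per column.
#'
#' @param frame preprocessed frame (matrix in [0, 1]).
#' @param init initial contour, list with \code{upper}/\code{lower} row
#'   coordinates per column (see \code{\link{contour_from_mask}}); must lie
#'   within the capture range of the true edge.
#' @param alpha smoothness weight.
#' @param gamma step size of the implicit update.
#' @param sigma Gaussian smoothing of the edge-energy image, px.
#' @param max_iter maximum iterations.
#' @param tol convergence threshold on the max contour displacement per
#'   iteration, px.
#' @return object of class \code{wall_contour}: \code{upper}, \code{lower},
#'   \code{x_px} (column centers), \code{Y_px}, \code{polyline} (closed,
#'   n x 2, columns x/y), \code{iterations}. Non-convergence raises a
#'   condition of class \code{segmentation_error} carrying the last contour.
#' @export
segment_wall <- function(frame, init, alpha = 2, gamma = 1, sigma = 2,
                         max_iter = 400, tol = 0.02) {
  nr <- nrow(frame); nc <- ncol(frame)
  stopifnot(length(init$upper) == nc, length(init$lower) == nc)
  gy <- rbind(frame[2, ] - frame[1, ],
              (frame[-(1:2), ] - frame[-((nr - 1):nr), ]) / 2,
              frame[nr, ] - frame[nr - 1, ])
  E <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(abs(gy))),
                                           sigma = sigma)))
  # vertical derivative of the edge energy (the snake's external force)
  dE <- rbind(E[2, ] - E[1, ],
              (E[-(1:2), ] - E[-((nr - 1):nr), ]) / 2,
              E[nr, ] - E[nr - 1, ])
  # implicit smoothness operator (I + gamma*alpha*D'D), D = second difference
  D <- diff(diag(nc), differences = 2)
  M <- diag(nc) + gamma * alpha * crossprod(D)
  ch <- chol(M)
  cols <- seq_len(nc)
  evolve <- function(y) {
    for (it in seq_len(max_iter)) {
      f <- .sample_rows(dE, y, cols)
      y_new <- backsolve(ch, forwardsolve(t(ch), y + gamma * f))
      y_new <- pmin(pmax(y_new, 1), nr)
      if (max(abs(y_new - y)) < tol) return(list(y = y_new, it = it, ok = TRUE))
      y <- y_new
    }
    list(y = y, it = max_iter, ok = FALSE)
  }
  up <- evolve(init$upper)
  lo <- evolve(init$lower)
  res <- list(upper = up$y, lower = lo$y, x_px = cols - 0.5,
              Y_px = lo$y - up$y,
              polyline = rbind(cbind(cols - 0.5, up$y),
                               cbind(rev(cols) - 0.5, rev(lo$y))),
              iterations = max(up$it, lo$it))
  class(res) <- "wall_contour"
  if (!up$ok || !lo$ok) {
    cnd <- structure(
      class = c("segmentation_error", "error", "condition"),
      list(message = sprintf("active contour did not converge in %d iterations",
                             max_iter),
           call = sys.call(-1), contour = res))
    stop(cnd)
  }
  res
}

#' Transverse lumen extent at requested stations
#' @param contour a \code{wall_contour}.
#' @param x_px axial stations, px.
#' @return Y at the stations, px.
#' @export
wall_Y <- function(contour, x_px) {
  stopifnot(inherits(contour, "wall_contour"))
  if (any(x_px < min(contour$x_px) - 0.5 | x_px > max(contour$x_px) + 0.5)) {
    stop("station outside the segmented range")
  }
  stats::approx(contour$x_px, contour$Y_px, x_px, rule = 2)$y
}

#' Wall deformation relative to diastole
#'
#' Relative circumferential variation of the wall dimension with respect to
#' its value at the diastolic reference time:
#' \eqn{\delta(x, t) = Y(x, t) - Y(x, t_0)}, also returned normalized by
#' \eqn{Y(x, t_0)} in percent (the form used for the circular cross-sections
#' of the idealized phantom).
#'
#' @param Y matrix of transverse extents, stations x times (px or mm).
#' @param t0 index of the diastolic reference column.
#' @return list with \code{delta} (same units as Y) and \code{delta_pct}.
#' @export
delta_deformation <- function(Y, t0 = 1) {
  Y <- as.matrix(Y)
  if (t0 < 1 || t0 > ncol(Y)) stop("diastolic reference index outside series")
  ref <- Y[, t0]
  if (any(!is.finite(ref)) || any(ref <= 0)) stop("invalid diastolic reference")
  delta <- Y - ref
  list(delta = delta, delta_pct = 100 * delta / ref)
}

# --- multi-pass PIV ----------------------------------------------------------

#' Interrogation-window grid
#'
#' Window top-left corners and centers for a given image size, window size
#' and overlap. The final-pass grid spacing is
#' \code{window * (1 - overlap)} px.
#'
#' @param dim image dim, \code{c(nrow, ncol)}.
#' @param window window size, px.
#' @param overlap fractional overlap in [0, 1).
#' @return list with \code{x0}, \code{y0} (top-left, 1-based), \code{x_px},
#'   \code{y_px} (centers), \code{window}, \code{step}.
#' @export
piv_grid <- function(dim, window, overlap = 0.5) {
  stopifnot(window >= 4, overlap >= 0, overlap < 1)
  if (window > min(dim)) stop("interrogation window larger than the image")
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  y0 <- seq(1L, dim[1] - window + 1L, by = step)
  x0 <- seq(1L, dim[2] - window + 1L, by = step)
  list(x0 = x0, y0 = y0,
       x_px = x0 + window / 2 - 0.5, y_px = y0 + window / 2 - 0.5,
       window = window, step = step)
}

# circular FFT cross-correlation of two zero-mean windows; returns the
# shifted plane (zero displacement at center) and the center index
.xcorr_plane <- function(a, b) {
  w <- nrow(a)
  p <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) / w^2
  half <- w / 2
  idx <- c((half + 1):w, 1:half)
  list(plane = p[idx, idx], center = half + 1)
}

# three-point Gaussian sub-pixel fit along one axis
.gauss3 <- function(cm, c0, cp) {
  eps <- 1e-12
  cm <- max(cm, eps); c0 <- max(c0, eps); cp <- max(cp, eps)
  den <- 2 * (log(cm) + log(cp) - 2 * log(c0))
  if (abs(den) < 1e-300) return(0)
  d <- (log(cm) - log(cp)) / den
  max(min(d, 1), -1)
}

# peak location (sub-pixel) and peak-ratio SNR from a shifted plane
.peak_analysis <- function(plane, center) {
  w <- nrow(plane)
  i <- which.max(plane)
  pr <- ((i - 1) %% w) + 1
  pc <- ((i - 1) %/% w) + 1
  peak1 <- plane[pr, pc]
  # sub-pixel refinement (clamped at the plane border)
  dr <- dc <- 0
  if (pr > 1 && pr < w) dr <- .gauss3(plane[pr - 1, pc], peak1, plane[pr + 1, pc])
  if (pc > 1 && pc < w) dc <- .gauss3(plane[pr, pc - 1], peak1, plane[pr, pc + 1])
  # second peak outside a 3x3 exclusion zone
  ex <- plane
  ex[max(1, pr - 1):min(w, pr + 1), max(1, pc - 1):min(w, pc + 1)] <- -Inf
  peak2 <- max(ex)
  snr <- if (peak2 > 0) peak1 / peak2 else Inf
  list(u = pc - center + dc, v = pr - center + dr, snr = snr)
}

# bilinear interpolation of a vector grid to a dense pixel field, with
# constant extrapolation beyond the outer window centers
.dense_predictor <- function(centers_x, centers_y, U, nr, nc) {
  U[!is.finite(U)] <- 0
  wx <- .interp_weights(centers_x, seq_len(nc) - 0.5)
  wy <- .interp_weights(centers_y, seq_len(nr) - 0.5)
  wy %*% U %*% t(wx)
}

# linear ramp from 0 at the lumen boundary to 1 at half-window distance,
# 0 outside the lumen (distance transform of the mask)
.wall_taper <- function(mask, half_window) {
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(t(mask * 1.0))))
  pmin(t(d) / half_window, 1)
}

# sparse-style linear interpolation weight matrix (query x knots)
.interp_weights <- function(knots, query) {
  n <- length(knots)
  W <- matrix(0, length(query), n)
  q <- pmin(pmax(query, knots[1]), knots[n])
  i0 <- pmax(1L, pmin(n - 1L, findInterval(q, knots)))
  w <- (q - knots[i0]) / (knots[i0 + 1] - knots[i0])
  W[cbind(seq_along(q), i0)] <- 1 - w
  W[cbind(seq_along(q), i0 + 1L)] <- W[cbind(seq_along(q), i0 + 1L)] + w
  W
}

# Catmull-Rom bicubic image warp: out(r, c) = img(r + dv(r,c), c + du(r,c))
.warp_bicubic <- function(img, du, dv) {
  nr <- nrow(img); nc <- ncol(img)
  rq <- matrix(rep(seq_len(nr), nc), nr, nc) + dv
  cq <- matrix(rep(seq_len(nc), each = nr), nr, nc) + du
  rq <- pmin(pmax(rq, 1), nr); cq <- pmin(pmax(cq, 1), nc)
  r0 <- floor(rq); c0 <- floor(cq)
  fr <- rq - r0; fc <- cq - c0
  ck <- function(f) {
    # Catmull-Rom kernel weights for offsets -1..2 at fraction f
    list(w0 = ((-0.5 * f + 1) * f - 0.5) * f,
         w1 = (1.5 * f - 2.5) * f * f + 1,
         w2 = ((-1.5 * f + 2) * f + 0.5) * f,
         w3 = (0.5 * f - 0.5) * f * f)
  }
  wr <- ck(fr); wc <- ck(fc)
  out <- matrix(0, nr, nc)
  wrl <- list(wr$w0, wr$w1, wr$w2, wr$w3)
  wcl <- list(wc$w0, wc$w1, wc$w2, wc$w3)
  for (j in 0:3) {
    cj <- pmin(pmax(c0 + j - 1, 1), nc)
    col_acc <- matrix(0, nr, nc)
    for (i in 0:3) {
      ri <- pmin(pmax(r0 + i - 1, 1), nr)
      col_acc <- col_acc + wrl[[i + 1]] * img[cbind(as.vector(ri),
                                                    as.vector(cj))]
    }
    out <- out + wcl[[j + 1]] * col_acc
  }
  out
}

#' Multi-pass FFT cross-correlation PIV with window deformation
#'
#' Estimates the displacement field between a double-exposure image pair by
#' FFT-based cross-correlation over a coarse-to-fine sequence of
#' interrogation windows (default 128/64/32 px, 50\% overlap). After each
#' pass the validated field is interpolated to a dense pixel-wise predictor
#' (bilinear) used to deform frame B onto frame A (bicubic image
#' interpolation) before the next correlation; the sub-pixel peak is located
#' with a three-point Gaussian fit per axis. Windows whose out-of-lumen mask
#' coverage exceeds 50\% emit no vector. A peak-ratio signal-to-noise value
#' is recorded per vector.
#'
#' @param a,b frames (numeric matrices, rows = y, cols = x), frame A first.
#' @param mask optional logical matrix, TRUE inside the lumen.
#' @param passes window sizes, px, coarse to fine.
#' @param overlap fractional window overlap.
#' @param scale image scale, px/mm (for mm coordinates and m/s velocities).
#' @param dt_s pulse separation, s (for velocities).
#' @param origin_mm mm coordinates of the (x, y) image origin (top-left
#'   pixel corner); y is measured from the image top like the row index.
#' @return object of class \code{vector_field}: \code{x_px}, \code{y_px}
#'   (grid centers), matrices \code{u_px}, \code{v_px}, \code{snr},
#'   \code{valid}, \code{replaced}, \code{mask_frac}, plus \code{x_mm},
#'   \code{y_mm}, \code{u_ms}, \code{v_ms} when \code{scale}/\code{dt_s} are
#'   supplied. NA displacements mark masked windows.
#' @export
piv_multipass <- function(a, b, mask = NULL, passes = c(128, 64, 32),
                          overlap = 0.5, scale = NULL, dt_s = NULL,
                          origin_mm = c(0, 0)) {
  stopifnot(all(dim(a) == dim(b)))
  if (!is.null(mask)) stopifnot(all(dim(mask) == dim(a)))
  nr <- nrow(a); nc <- ncol(a)
  if (max(passes) > min(nr, nc)) stop("interrogation window larger than the image")
  pred_u <- matrix(0, nr, nc); pred_v <- matrix(0, nr, nc)
  field <- NULL
  for (p in seq_along(passes)) {
    w <- passes[p]
    g <- piv_grid(c(nr, nc), w, overlap)
    bw <- if (p == 1) b else .warp_bicubic(b, pred_u, pred_v)
    ny <- length(g$y0); nx <- length(g$x0)
    U <- V <- S <- matrix(NA_real_, ny, nx)
    MF <- matrix(0, ny, nx)
    for (iy in seq_len(ny)) {
      rows <- g$y0[iy]:(g$y0[iy] + w - 1)
      for (ix in seq_len(nx)) {
        cols <- g$x0[ix]:(g$x0[ix] + w - 1)
        if (!is.null(mask)) {
          mf <- 1 - mean(mask[rows, cols])
          MF[iy, ix] <- mf
          if (mf > 0.5) next
        }
        wa <- a[rows, cols]; wb <- bw[rows, cols]
        wa <- wa - mean(wa); wb <- wb - mean(wb)
        if (all(wa == 0) || all(wb == 0)) next
        xc <- .xcorr_plane(wa, wb)
        pk <- .peak_analysis(xc$plane, xc$center)
        # residual on the deformed frame + predictor at the window center
        pu <- pred_u[g$y0[iy] + w / 2, g$x0[ix] + w / 2]
        pv <- pred_v[g$y0[iy] + w / 2, g$x0[ix] + w / 2]
        U[iy, ix] <- pk$u + pu
        V[iy, ix] <- pk$v + pv
        S[iy, ix] <- pk$snr
      }
    }
    field <- structure(
      list(x_px = g$x_px, y_px = g$y_px, u_px = U, v_px = V, snr = S,
           valid = is.finite(U), replaced = matrix(FALSE, ny, nx),
           mask_frac = MF, window = w, step = g$step,
           scale = scale, dt_s = dt_s, origin_mm = origin_mm),
      class = "vector_field")
    if (p < length(passes)) {
      if (!any(is.finite(U))) next          # fully masked: keep a zero predictor
      vf <- validate_vectors(field)
      uu <- vf$u_px; vv <- vf$v_px
      pred_u <- .dense_predictor(g$x_px, g$y_px, uu, nr, nc)
      pred_v <- .dense_predictor(g$x_px, g$y_px, vv, nr, nc)
      if (!is.null(mask)) {
        # no-slip taper: the predictor decays linearly to zero at the wall
        # instead of carrying the core displacement into the boundary layer
        taper <- .wall_taper(mask, passes[p + 1] / 2)
        pred_u <- pred_u * taper
        pred_v <- pred_v * taper
      }
    }
  }
  .finalize_field(field)
}

# attach mm coordinates and m/s velocities when scale/dt are known
.finalize_field <- function(field) {
  if (!is.null(field$scale)) {
    field$x_mm <- field$origin_mm[1] + field$x_px / field$scale
    field$y_mm <- field$origin_mm[2] + field$y_px / field$scale
    if (!is.null(field$dt_s)) {
      fac <- 1 / field$scale / field$dt_s / 1000   # px -> m/s
      field$u_ms <- field$u_px * fac
      field$v_ms <- field$v_px * fac
    }
  }
  field
}

#' Three-criterion vector validation
#'
#' Flags a vector as invalid when any of: (i) a velocity component departs
#' from the global mean of the field by more than \code{global_k} standard
#' deviations; (ii) its residual to the neighborhood median exceeds
#' \code{median_k} times the median neighbor residual (normalized median
#' test with regularization \code{eps_px}); (iii) its correlation
#' signal-to-noise ratio falls below \code{snr_min}. Invalid vectors are
#' replaced by the mean of the valid vectors in their neighborhood and
#' flagged \code{replaced}. Vectors already flagged as replaced by a
#' previous run are left untouched, which makes repeated validation stable.
#'
#' @param field a \code{vector_field}.
#' @param neighborhood odd neighborhood size (>= 3) for the median test and
#'   the replacement.
#' @param global_k global threshold in standard deviations.
#' @param median_k local normalized-median threshold.
#' @param snr_min minimum acceptable signal-to-noise ratio.
#' @param eps_px regularization of the median-residual denominator, px.
#' @return the field with updated \code{valid}/\code{replaced} flags and
#'   replaced displacements; attribute \code{invalid_rate} holds the
#'   fraction of (pre-replacement) invalid vectors among the tested ones.
#' @export
validate_vectors <- function(field, neighborhood = 3, global_k = 5,
                             median_k = 3, snr_min = 1.25, eps_px = 0.1) {
  stopifnot(inherits(field, "vector_field"))
  if (neighborhood < 3 || neighborhood %% 2 == 0) {
    stop("neighborhood must be an odd size >= 3")
  }
  U <- field$u_px; V <- field$v_px; S <- field$snr
  present <- is.finite(U) & is.finite(V)
  if (!any(present)) stop("empty vector field")
  testable <- present & !field$replaced
  h <- (neighborhood - 1) / 2
  ny <- nrow(U); nx <- ncol(U)

  gm_u <- mean(U[present]); gs_u <- stats::sd(U[present])
  gm_v <- mean(V[present]); gs_v <- stats::sd(V[present])
  if (!is.finite(gs_u)) gs_u <- 0
  if (!is.finite(gs_v)) gs_v <- 0
  bad_global <- testable &
    (abs(U - gm_u) > global_k * gs_u | abs(V - gm_v) > global_k * gs_v)

  bad_median <- matrix(FALSE, ny, nx)
  med_test <- function(M, iy, ix) {
    ys <- max(1, iy - h):min(ny, iy + h)
    xs <- max(1, ix - h):min(nx, ix + h)
    nb <- M[ys, xs]
    nb[which(ys == iy), which(xs == ix)] <- NA   # exclude the center
    nb <- nb[is.finite(nb)]
    if (length(nb) < 3) return(FALSE)
    med <- stats::median(nb)
    rm_ <- stats::median(abs(nb - med))
    abs(M[iy, ix] - med) / (rm_ + eps_px) > median_k
  }
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    if (!testable[iy, ix]) next
    if (med_test(U, iy, ix) || med_test(V, iy, ix)) bad_median[iy, ix] <- TRUE
  }
  bad_snr <- testable & is.finite(S) & (S < snr_min)
  bad <- bad_global | bad_median | bad_snr
  rate <- sum(bad) / sum(testable)

  valid <- field$valid
  valid[testable] <- !bad[testable]
  # replacement: mean of valid neighbors
  Ur <- U; Vr <- V
  repl <- field$replaced
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    if (!bad[iy, ix]) next
    ys <- max(1, iy - h):min(ny, iy + h)
    xs <- max(1, ix - h):min(nx, ix + h)
    ok <- valid[ys, xs] & is.finite(U[ys, xs])
    ok[which(ys == iy), which(xs == ix)] <- FALSE
    if (any(ok)) {
      Ur[iy, ix] <- mean(U[ys, xs][ok])
      Vr[iy, ix] <- mean(V[ys, xs][ok])
      repl[iy, ix] <- TRUE
    }
  }
  field$u_px <- Ur; field$v_px <- Vr
  field$valid <- valid; field$replaced <- repl
  field <- .finalize_field(field)
  attr(field, "invalid_rate") <- rate
  field
}

#' Write a vector field as a per-pair tabular text file
#'
#' Columns: x_px, y_px, x_mm, y_mm, u_ms, v_ms, snr, valid, replaced.
#'
#' @param field a \code{vector_field} (with scale and dt set).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_vector_field_csv <- function(field, path) {
  stopifnot(inherits(field, "vector_field"), !is.null(field$u_ms))
  d <- data.frame(
    x_px = rep(field$x_px, each = length(field$y_px)),
    y_px = rep(field$y_px, length(field$x_px)),
    x_mm = rep(field$x_mm, each = length(field$y_mm)),
    y_mm = rep(field$y_mm, length(field$x_mm)),
    u_ms = as.vector(field$u_ms), v_ms = as.vector(field$v_ms),
    snr = as.vector(field$snr),
    valid = as.vector(field$valid), replaced = as.vector(field$replaced))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
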