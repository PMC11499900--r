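#' Idealized axisymmetric AAA geometry
#'
#' Constructs the parametric description of an idealized axisymmetric
#' abdominal aortic aneurysm (AAA) lumen: a straight parent vessel of inner
#' diameter \code{d} carrying a cosine-shaped fusiform bulge of length
#' \code{aspect_ratio * d} and maximum diameter \code{dilation_ratio * d},
#' centered at the axial origin.
#'
#' The bulge profile (lumen radius as a function of axial position \code{x},
#' origin at the bulge center) is
#' \deqn{\Gamma(x) = d^* \cos\left(\frac{\pi x}{2 x^*}\right) + d/2,
#'   \quad x \in [-x^*, x^*],}
#' with half-length \eqn{x^* = 0.5\,(L/d)\,d} and amplitude
#' \eqn{d^* = 0.5\,(D/d - 1)\,d}; outside the bulge window the radius is the
#' parent value \eqn{d/2}.
#'
#' @param d parent-vessel inner diameter, mm.
#' @param aspect_ratio bulge length over parent diameter, L/d (dimensionless).
#' @param dilation_ratio maximum bulge diameter over parent diameter, D/d
#'   (dimensionless, must be >= 1).
#' @param total_length overall model length, mm.
#' @param wall_thickness phantom wall thickness, mm (used only for rendering
#'   wall-reflection artifacts, never by the analysis).
#' @return An object of class \code{aaa_geometry} with the input fields plus
#'   the derived bulge half-length \code{x_star} (mm) and bulge amplitude
#'   \code{d_star} (mm).
#' @examples
#' geom <- aaa_geometry()
#' bulge_radius(geom, 0)     # maximum lumen radius at the bulge center
#' bulge_radius(geom, 100)   # parent-vessel radius downstream
#' @export
aaa_geometry <- function(d = 20, aspect_ratio = 2.9, dilation_ratio = 1.9,
                         total_length = 250, wall_thickness = 1.8) {
  stopifnot(d > 0, aspect_ratio > 0, dilation_ratio >= 1,
            total_length >= aspect_ratio * d, wall_thickness >= 0)
  g <- list(
    d = d,
    aspect_ratio = aspect_ratio,
    dilation_ratio = dilation_ratio,
    total_length = total_length,
    wall_thickness = wall_thickness,
    x_star = 0.5 * aspect_ratio * d,
    d_star = 0.5 * (dilation_ratio - 1) * d
  )
  class(g) <- "aaa_geometry"
  g
}

#' @export
print.aaa_geometry <- function(x, ...) {
  cat("Idealized axisymmetric AAA geometry\n")
  cat(sprintf("  parent diameter d      : %g mm\n", x$d))
  cat(sprintf("  aspect ratio L/d       : %g\n", x$aspect_ratio))
  cat(sprintf("  dilation ratio D/d     : %g\n", x$dilation_ratio))
  cat(sprintf("  total length           : %g mm\n", x$total_length))
  cat(sprintf("  wall thickness         : %g mm\n", x$wall_thickness))
  cat(sprintf("  bulge half-length x*   : %g mm\n", x$x_star))
  cat(sprintf("  bulge amplitude d*     : %g mm\n", x$d_star))
  invisible(x)
}

#' Lumen radius at an axial station
#'
#' Evaluates the lumen radius \eqn{\Gamma(x)} of an idealized AAA geometry at
#' axial coordinate \code{x} (mm, origin at the bulge center, positive
#' downstream). Vectorized over \code{x}.
#'
#' @param geom an \code{\link{aaa_geometry}}.
#' @param x axial coordinate(s), mm; must lie within
#'   \code{[-total_length/2, total_length/2]}.
#' @return Lumen radius in mm, same length as \code{x}.
#' @export
bulge_radius <- function(geom, x) {
  stopifnot(inherits(geom, "aaa_geometry"))
  if (any(abs(x) > geom$total_length / 2 + 1e-9)) {
    stop("axial coordinate outside the model length [-",
         geom$total_length / 2, ", ", geom$total_length / 2, "] mm")
  }
  r <- rep(geom$d / 2, length(x))
  inside <- abs(x) <= geom$x_star
  r[inside] <- geom$d_star * cos(pi * x[inside] / (2 * geom$x_star)) + geom$d / 2
  r
}

#' Rasterize a mid-plane lumen mask
#'
#' Renders the binary mid-plane (light-sheet plane through the axis) lumen
#' mask of an idealized AAA geometry over an axial window, at a given image
#' scale. Pixel centers sit at half-integer positions; image columns map to
#' the axial coordinate and rows to the transverse coordinate, with the vessel
#' axis at the vertical center of the image.
#'
#' @param geom an \code{\link{aaa_geometry}}.
#' @param window length-2 numeric, axial range \code{c(x0, x1)} in mm
#'   (bulge-centered coordinates).
#' @param scale image scale, px/mm.
#' @param size image size in px as \code{c(width, height)}; defaults to the
#'   smallest image covering the window and the maximum lumen diameter plus
#'   wall.
#' @return A list of class \code{lumen_mask} with elements \code{mask}
#'   (logical matrix, rows = y, cols = x, TRUE inside the lumen), \code{x_mm}
#'   (axial coordinate of each column center), \code{y_mm} (transverse
#'   coordinate of each row center, 0 on the axis), \code{scale}, and
#'   \code{window}.
#' @export
lumen_mask <- function(geom, window, scale, size = NULL) {
  stopifnot(inherits(geom, "aaa_geometry"), length(window) == 2, scale > 0)
  window <- sort(window)
  if (any(abs(window) > geom$total_length / 2 + 1e-9)) {
    stop("mask window extends outside the model length")
  }
  if (is.null(size)) {
    w <- ceiling((window[2] - window[1]) * scale)
    h <- ceiling((geom$dilation_ratio * geom$d + 2 * geom$wall_thickness + 2) * scale)
    size <- c(w, h)
  }
  size <- as.integer(round(size))
  if (any(size < 1)) stop("mask window and scale produce an empty image")
  nx <- size[1]; ny <- size[2]
  x_mm <- window[1] + (seq_len(nx) - 0.5) / scale
  y_mm <- ((seq_len(ny) - 0.5) - ny / 2) / scale
  r_at_x <- bulge_radius(geom, pmin(pmax(x_mm, -geom$total_length / 2),
                                    geom$total_length / 2))
  mask <- outer(abs(y_mm), r_at_x, `<=`)
  structure(list(mask = mask, x_mm = x_mm, y_mm = y_mm,
                 scale = scale, window = window),
            class = "lumen_mask")
}

#' Write a lumen mask as an 8-bit PNG (0/255)
#'
#' @param m a \code{lumen_mask}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_mask_png <- function(m, path) {
  stopifnot(inherits(m, "lumen_mask"))
  png::writePNG(m$mask * 1.0, path)
  invisible(path)
}

#' Read a 0/255 PNG mask back as a logical matrix
#' @param path PNG file path.
#' @return logical matrix, TRUE inside the lumen.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}
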