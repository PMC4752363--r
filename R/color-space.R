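# CIE color conversions. Images are linear RGB with Rec. 709 primaries and
# a D65 white; the reference white defaults to the XYZ of linear RGB
# (1, 1, 1) so the white point maps exactly to L* = 100, a* = b* = 0.

# linear Rec.709 RGB -> CIE XYZ (D65)
RGB_TO_XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)

#' Reference white of the package's RGB model
#'
#' XYZ coordinates of linear RGB (1, 1, 1) under the Rec. 709 primaries
#' (a D65 white).
#' @return Length-3 numeric vector (X, Y, Z).
#' @export
d65_white <- function() as.vector(RGB_TO_XYZ %*% rep(1, 3))

# CIE 1976 nonlinearity and inverse
lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}
lab_f_inv <- function(u) {
  d <- 6 / 29
  ifelse(u > d, u^3, 3 * d^2 * (u - 4 / 29))
}

as_pixel_matrix <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    stopifnot(dim(x)[3] >= 3L)
    matrix(x[, , 1:3], ncol = 3L)
  } else if (is.matrix(x) && ncol(x) == 3L) {
    x
  } else stop("expected an h x w x 3 array or an n x 3 matrix of pixels",
              call. = FALSE)
}

#' Convert linear RGB pixels to CIELAB
#'
#' Applies the Rec. 709 linear-RGB-to-XYZ matrix and then the CIE 1976
#' L*a*b* transform with the given reference white. Input values outside
#' `[0, 1]` are clipped with a warning. For in-gamut input, L* lies in
#' `[0, 100]`.
#'
#' @param pixels An `n x 3` matrix of linear RGB pixels, or an
#'   `h x w x 3` image array (flattened to pixels).
#' @param white Reference white as an XYZ triple; defaults to the XYZ of
#'   linear RGB (1, 1, 1) (D65).
#' @return An `n x 3` matrix with columns `L`, `a`, `b`.
#' @examples
#' rgb_to_lab(matrix(c(1, 1, 1), 1))      # L* = 100 at the white point
#' rgb_to_lab(matrix(c(0.18, 0.18, 0.18), 1))
#' @export
rgb_to_lab <- function(pixels, white = d65_white()) {
  px <- as_pixel_matrix(pixels)
  stopifnot(length(white) == 3L, all(white > 0))
  if (any(px < 0 | px > 1)) {
    warning("RGB values outside [0, 1] clipped before conversion")
    px <- pmin(pmax(px, 0), 1)
  }
  xyz <- px %*% t(RGB_TO_XYZ)
  fx <- lab_f(xyz[, 1] / white[1])
  fy <- lab_f(xyz[, 2] / white[2])
  fz <- lab_f(xyz[, 3] / white[3])
  out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  rownames(out) <- NULL
  out
}

#' Convert CIELAB to linear RGB
#'
#' Inverse of [rgb_to_lab()]; used by the egg-image renderer to realize a
#' requested background colour. Out-of-gamut results are an error when
#' `clip = FALSE`, otherwise clipped to `[0, 1]`.
#'
#' @param lab An `n x 3` matrix (L*, a*, b*) or length-3 vector.
#' @param white Reference white (XYZ triple).
#' @param clip Clip out-of-gamut channels instead of erroring.
#' @return An `n x 3` matrix of linear RGB values in `[0, 1]`.
#' @export
lab_to_rgb <- function(lab, white = d65_white(), clip = FALSE) {
  if (is.vector(lab)) lab <- matrix(lab, ncol = 3L)
  stopifnot(ncol(lab) == 3L)
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  xyz <- cbind(lab_f_inv(fx) * white[1], lab_f_inv(fy) * white[2],
               lab_f_inv(fz) * white[3])
  rgb <- xyz %*% t(solve(RGB_TO_XYZ))
  if (any(rgb < -1e-9 | rgb > 1 + 1e-9)) {
    if (!clip) stop("CIELAB colour outside the linear-RGB gamut", call. = FALSE)
  }
  pmin(pmax(rgb, 0), 1)
}

# Rec. 709 luminance of a linear RGB image array (grayscale for
# thresholding).
rgb_luminance <- function(image) {
  stopifnot(is.array(image), length(dim(image)) == 3L)
  0.2126729 * image[, , 1] + 0.7151522 * image[, , 2] + 0.0721750 * image[, , 3]
}
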