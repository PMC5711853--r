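# Pixel-level colour transformations: device sRGB -> HSI / CIELab / CIELuv.
#
# Conventions used throughout:
#  * input pixels are 8-bit sRGB (0-255) unless `max_value = 1` marks them as
#    pre-normalised reals in [0, 1];
#  * HSI is computed on the gamma-encoded (device) channels, as plot-colour
#    software does, with I = (r + g + b)/3 and S = 1 - min(r, g, b)/I;
#  * CIELab and CIELuv are computed from gamma-decoded linear RGB through
#    CIE XYZ with the D65 white point; no further chromatic adaptation.

# sRGB -> XYZ (D65) primaries, rows sum to the D65 white point
.SRGB_TO_XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

# White point taken as the matrix row sums (D65 to 7 decimals), so that
# neutral greys collapse to a* = b* = u* = v* = 0 exactly.
.D65 <- c(X = sum(.SRGB_TO_XYZ[1, ]), Y = sum(.SRGB_TO_XYZ[2, ]),
          Z = sum(.SRGB_TO_XYZ[3, ]))

# Coerce pixels to an n x 3 matrix of channel values and validate range.
.pixel_matrix <- function(pixel, max_value = 255) {
  if (is.null(dim(pixel))) {
    if (length(pixel) %% 3L != 0L) {
      stop("pixels must have exactly 3 channels", call. = FALSE)
    }
    pixel <- matrix(pixel, ncol = 3L, byrow = TRUE)
  }
  pixel <- as.matrix(pixel)
  if (ncol(pixel) != 3L) {
    stop("pixels must have exactly 3 channels", call. = FALSE)
  }
  if (anyNA(pixel)) stop("pixel channels must not be NA", call. = FALSE)
  if (any(pixel < 0) || any(pixel > max_value)) {
    stop(sprintf("pixel channels must lie in [0, %s]", format(max_value)),
         call. = FALSE)
  }
  pixel
}

#' Decode sRGB channel values to linear RGB
#'
#' Applies the standard sRGB electro-optical transfer function (the piecewise
#' gamma curve with linear toe) to 8-bit channel values, mapping 0 to 0 and
#' 255 to 1 monotonically.
#'
#' @param pixel A length-3 vector, or an n x 3 matrix, of channel values.
#' @param max_value Declared channel range: 255 (default, 8-bit) or 1 for
#'   pre-normalised input.
#' @return Linear RGB values in `[0, 1]`, same shape as the input.
#' @examples
#' decode_srgb(c(0, 128, 255))
#' @export
decode_srgb <- function(pixel, max_value = 255) {
  x <- .pixel_matrix(pixel, max_value) / max_value
  lin <- ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
  if (is.null(dim(pixel)) && length(pixel) == 3L) c(lin) else lin
}

.rgb_to_xyz <- function(pixel, max_value = 255) {
  lin <- .pixel_matrix(pixel, max_value) / max_value
  lin <- ifelse(lin <= 0.04045, lin / 12.92, ((lin + 0.055) / 1.055)^2.4)
  lin %*% t(.SRGB_TO_XYZ)
}

# CIE L* companding of a ratio t = X/Xn etc.
.lab_f <- function(t) {
  ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}

#' Convert sRGB pixels to HSI (hue-saturation-intensity)
#'
#' Hue is the standard colour angle on `[0, 360)` with red at 0, yellow at
#' 60, green at 120 and cyan at 180 degrees. Intensity is the mean of the
#' normalised channels and saturation is `1 - min(r, g, b) / I`. Achromatic
#' pixels (r = g = b) have undefined hue and are assigned hue 0 with
#' saturation 0; downstream angular averaging should weight them out.
#'
#' @inheritParams decode_srgb
#' @return A data.frame with columns `hue_deg`, `saturation`, `intensity`
#'   (one row per pixel).
#' @examples
#' rgb_to_hsi(c(0, 255, 0)) # pure green: hue 120
#' @export
rgb_to_hsi <- function(pixel, max_value = 255) {
  x <- .pixel_matrix(pixel, max_value) / max_value
  r <- x[, 1L]; g <- x[, 2L]; b <- x[, 3L]
  intensity <- (r + g + b) / 3
  mn <- pmin(r, g, b)
  saturation <- ifelse(intensity > 0, 1 - mn / intensity, 0)

  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  achromatic <- den < .Machine$double.eps^0.5
  cosang <- ifelse(achromatic, 1, pmin(1, pmax(-1, num / ifelse(achromatic, 1, den))))
  theta <- acos(cosang) * 180 / pi
  hue <- ifelse(b <= g, theta, 360 - theta)
  hue <- ifelse(achromatic, 0, hue %% 360)
  data.frame(hue_deg = hue, saturation = saturation, intensity = intensity)
}

#' Convert sRGB pixels to CIELab
#'
#' Gamma-decodes to linear RGB, converts to CIE XYZ under D65 and applies the
#' CIELab companding. `a_star` scales green (negative) to red (positive),
#' `b_star` blue (negative) to yellow (positive); neutral greys map to
#' `a* = b* = 0` exactly.
#'
#' @inheritParams decode_srgb
#' @return A data.frame with columns `L_star`, `a_star`, `b_star`.
#' @examples
#' rgb_to_cielab(c(0, 255, 0)) # a* strongly negative
#' @export
rgb_to_cielab <- function(pixel, max_value = 255) {
  xyz <- .rgb_to_xyz(pixel, max_value)
  fx <- .lab_f(xyz[, 1L] / .D65[["X"]])
  fy <- .lab_f(xyz[, 2L] / .D65[["Y"]])
  fz <- .lab_f(xyz[, 3L] / .D65[["Z"]])
  data.frame(
    L_star = 116 * fy - 16,
    a_star = 500 * (fx - fy),
    b_star = 200 * (fy - fz)
  )
}

#' Convert sRGB pixels to CIELuv
#'
#' Same decoding chain as [rgb_to_cielab()] but with the CIELuv chromaticity
#' projection: `u_star` grows toward red, `v_star` toward yellow-green;
#' achromatic pixels map to `u* = v* = 0` exactly.
#'
#' @inheritParams decode_srgb
#' @return A data.frame with columns `L_star`, `u_star`, `v_star`.
#' @export
rgb_to_cieluv <- function(pixel, max_value = 255) {
  xyz <- .rgb_to_xyz(pixel, max_value)
  X <- xyz[, 1L]; Y <- xyz[, 2L]; Z <- xyz[, 3L]
  L <- 116 * .lab_f(Y / .D65[["Y"]]) - 16
  d <- X + 15 * Y + 3 * Z
  dn <- .D65[["X"]] + 15 * .D65[["Y"]] + 3 * .D65[["Z"]]
  up <- ifelse(d > 0, 4 * X / d, 4 * .D65[["X"]] / dn)
  vp <- ifelse(d > 0, 9 * Y / d, 9 * .D65[["Y"]] / dn)
  upn <- 4 * .D65[["X"]] / dn
  vpn <- 9 * .D65[["Y"]] / dn
  data.frame(
    L_star = L,
    u_star = 13 * L * (up - upn),
    v_star = 13 * L * (vp - vpn)
  )
}

#' Circular (vector) mean of hue angles
#'
#' Hue is angular, so per-plot averages must be taken on the unit circle:
#' each angle contributes a unit vector (optionally weighted) and the mean is
#' the angle of the vector sum. Pixels with zero weight (e.g. achromatic
#' pixels whose hue is undefined) drop out.
#'
#' @param hues Numeric vector of angles in degrees.
#' @param weights Optional nonnegative weights, recycled to `length(hues)`.
#' @return A single angle in `[0, 360)`.
#' @examples
#' circular_mean_hue(c(350, 10)) # 0, not 180
#' @export
circular_mean_hue <- function(hues, weights = NULL) {
  if (length(hues) == 0L) stop("no hues to average", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(hues))
  if (length(weights) != length(hues)) {
    weights <- rep_len(weights, length(hues))
  }
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  w <- sum(weights)
  if (w <= 0) stop("total weight must be positive", call. = FALSE)
  rad <- hues * pi / 180
  ang <- atan2(sum(weights * sin(rad)), sum(weights * cos(rad))) * 180 / pi
  ang <- ang %% 360
  if (360 - ang < 1e-9) ang <- 0
  ang
}
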