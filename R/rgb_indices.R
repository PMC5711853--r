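# Plot-level RGB vegetation indices.
#
# Ten indices per plot image: mean Intensity, circular-mean Hue, mean
# Saturation, mean Lightness (CIELab L*), mean a*, b*, u*, v*, and the two
# canopy-cover fractions GA (hue 60-180 degrees) and GGA (hue 80-180 degrees,
# excluding yellowish-green).

GA_HUE_WINDOW <- c(60, 180)
GGA_HUE_WINDOW <- c(80, 180)

# Flatten an rgb_image (or h x w x 3 array / n x 3 matrix) to an n x 3
# matrix of 8-bit values, applying an optional logical mask.
.flatten_pixels <- function(image, mask = NULL) {
  px <- if (inherits(image, "rgb_image")) image$pixels else image
  if (length(dim(px)) == 3L) {
    if (dim(px)[3L] != 3L) stop("image must have 3 channels", call. = FALSE)
    n <- prod(dim(px)[1:2])
    flat <- matrix(px, nrow = n, ncol = 3L)
    if (!is.null(mask)) {
      if (!identical(dim(mask), dim(px)[1:2])) {
        stop("mask shape must match image shape", call. = FALSE)
      }
      flat <- flat[as.vector(mask), , drop = FALSE]
    }
  } else {
    flat <- .pixel_matrix(px)
    if (!is.null(mask)) flat <- flat[as.vector(mask), , drop = FALSE]
  }
  if (nrow(flat) == 0L) stop("mask selects no pixels", call. = FALSE)
  flat
}

# Per-pixel hue/saturation plus the green classification used by GA/GGA.
# Achromatic pixels are never classified green (their hue is undefined).
.green_classes <- function(flat) {
  hsi <- rgb_to_hsi(flat)
  chromatic <- hsi$saturation > 0
  list(
    hsi = hsi,
    ga = chromatic & hsi$hue_deg >= GA_HUE_WINDOW[1] & hsi$hue_deg <= GA_HUE_WINDOW[2],
    gga = chromatic & hsi$hue_deg >= GGA_HUE_WINDOW[1] & hsi$hue_deg <= GGA_HUE_WINDOW[2]
  )
}

#' Green Area: canopy-cover fraction from hue thresholding
#'
#' Fraction of (masked) pixels whose hue lies in the 60-180 degree window,
#' i.e. yellow-green through bluish green — the classical proxy for green
#' canopy cover in plot images. Achromatic pixels are never counted green.
#'
#' @param image An [rgb_image()], an h x w x 3 array of 8-bit values, or an
#'   n x 3 pixel matrix.
#' @param mask Optional logical map of pixels to include (same shape as the
#'   image plane); must select at least one pixel.
#' @return A fraction in `[0, 1]`.
#' @export
green_area <- function(image, mask = NULL) {
  cls <- .green_classes(.flatten_pixels(image, mask))
  mean(cls$ga)
}

#' Greener Area: canopy cover excluding yellowish-green tones
#'
#' Like [green_area()] but with the stricter 80-180 degree hue window, so
#' chlorotic (yellowing) vegetation drops out. By construction
#' `greener_area(x) <= green_area(x)` for every image.
#'
#' @inheritParams green_area
#' @return A fraction in `[0, 1]`.
#' @export
greener_area <- function(image, mask = NULL) {
  cls <- .green_classes(.flatten_pixels(image, mask))
  mean(cls$gga)
}

#' Summarise a plot image into the ten RGB vegetation indices
#'
#' Reduces one plot's RGB image to a single row: mean Intensity, Saturation
#' (HSI, on `[0, 1]`), circular-mean Hue (degrees; achromatic pixels carry
#' zero weight), mean CIELab Lightness/a*/b*, mean CIELuv u*/v*, and the GA
#' and GGA cover fractions.
#'
#' @inheritParams green_area
#' @return A one-row data.frame with columns `intensity`, `hue_deg`,
#'   `saturation`, `lightness`, `a_star`, `b_star`, `u_star`, `v_star`,
#'   `ga`, `gga`, `n_pixels`.
#' @examples
#' img <- array(rep(c(60L, 160L, 40L), each = 16), dim = c(4, 4, 3))
#' summarize_rgb_plot(img)
#' @export
summarize_rgb_plot <- function(image, mask = NULL) {
  flat <- .flatten_pixels(image, mask)
  cls <- .green_classes(flat)
  hsi <- cls$hsi
  lab <- rgb_to_cielab(flat)
  luv <- rgb_to_cieluv(flat)
  hue_w <- as.numeric(hsi$saturation > 0)
  hue <- if (sum(hue_w) > 0) circular_mean_hue(hsi$hue_deg, hue_w) else 0
  data.frame(
    intensity = mean(hsi$intensity),
    hue_deg = hue,
    saturation = mean(hsi$saturation),
    lightness = mean(lab$L_star),
    a_star = mean(lab$a_star),
    b_star = mean(lab$b_star),
    u_star = mean(luv$u_star),
    v_star = mean(luv$v_star),
    ga = mean(cls$ga),
    gga = mean(cls$gga),
    n_pixels = nrow(flat)
  )
}
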