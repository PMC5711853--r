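# Independent reference implementations used as oracles. These are coded
# from the published definitions as plain scalar chains (loops, literal
# constants), deliberately separate from the package's vectorised code.

# Scalar sRGB (0-255) -> CIE XYZ with nominal D65 constants.
oracle_xyz <- function(rgb) {
  lin <- numeric(3)
  for (i in 1:3) {
    c01 <- rgb[i] / 255
    lin[i] <- if (c01 <= 0.04045) c01 / 12.92 else ((c01 + 0.055) / 1.055)^2.4
  }
  c(
    0.4124564 * lin[1] + 0.3575761 * lin[2] + 0.1804375 * lin[3],
    0.2126729 * lin[1] + 0.7151522 * lin[2] + 0.0721750 * lin[3],
    0.0193339 * lin[1] + 0.1191920 * lin[2] + 0.9503041 * lin[3]
  )
}

oracle_lab <- function(rgb) {
  wn <- c(0.95047, 1.0, 1.08883)
  xyz <- oracle_xyz(rgb)
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(xyz[1] / wn[1]); fy <- f(xyz[2] / wn[2]); fz <- f(xyz[3] / wn[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

oracle_luv <- function(rgb) {
  wn <- c(0.95047, 1.0, 1.08883)
  xyz <- oracle_xyz(rgb)
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  L <- 116 * f(xyz[2] / wn[2]) - 16
  den <- xyz[1] + 15 * xyz[2] + 3 * xyz[3]
  denn <- wn[1] + 15 * wn[2] + 3 * wn[3]
  up <- if (den > 0) 4 * xyz[1] / den else 4 * wn[1] / denn
  vp <- if (den > 0) 9 * xyz[2] / den else 9 * wn[2] / denn
  c(L = L, u = 13 * L * (up - 4 * wn[1] / denn),
    v = 13 * L * (vp - 9 * wn[2] / denn))
}

# Scalar hue angle in degrees from the acos definition; NA when achromatic.
oracle_hue <- function(rgb) {
  r <- rgb[1] / 255; g <- rgb[2] / 255; b <- rgb[3] / 255
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  if (den < 1e-12) return(NA_real_)
  theta <- acos(max(-1, min(1, 0.5 * ((r - g) + (r - b)) / den))) * 180 / pi
  if (b <= g) theta else 360 - theta
}

# Naive per-pixel counting loop for the hue-window cover fractions.
oracle_cover_fraction <- function(pixels, lo, hi) {
  d <- dim(pixels)
  n_in <- 0L
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      h <- oracle_hue(c(pixels[i, j, 1], pixels[i, j, 2], pixels[i, j, 3]))
      if (!is.na(h) && h >= lo && h <= hi) n_in <- n_in + 1L
    }
  }
  n_in / (d[1] * d[2])
}

# Literal transcriptions of the published multispectral index formulas,
# evaluated as expressions over band variables (and soil factor L).
INDEX_FORMULA_STRINGS <- c(
  ndvi  = "(B840 - B670)/(B840 + B670)",
  savi  = "(B840 - B670)/(B840 + B670 + L)*(1 + L)",
  osavi = "((1 + 0.16)*(B780 - B670))/((B780 + B670 + 0.16))",
  rdvi  = "(B840 - B670)/((B840 + B670)^(1/2))",
  evi   = "2.5*(B840 - B670)/(B840 + (6*B670) - (7.5*B450) + 1)",
  pri   = "(B550 - B570)/(B550 + B570)",
  mcari = "((B700 - B670) - 0.2*(B700 - B550))*B700/B670",
  tcari = "3*(B700 - B670)-0.2*(B700 - B550)*(B700/B670)",
  ari2  = "B840*(1/B550 - 1/B700)",
  cri2  = "1/B550 - 1/B700",
  wbi   = "(B840 - B670)/(B840 + B670)^(1/2)"
)

eval_formula_string <- function(name, bands, L = 0.5) {
  env <- new.env()
  for (wl in names(bands)) assign(paste0("B", wl), bands[[wl]], envir = env)
  assign("L", L, envir = env)
  eval(parse(text = INDEX_FORMULA_STRINGS[[name]]), envir = env)
}

random_band_vector <- function() {
  v <- stats::runif(length(canopyvi::SPECTRAL_WAVELENGTHS), 0.02, 0.95)
  stats::setNames(as.list(v), as.character(canopyvi::SPECTRAL_WAVELENGTHS))
}

random_rgb_image <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

# Frozen null simulation for the stepwise entry criterion: two independent
# candidate predictors at alpha 0.05 give an expected intercept-only rate
# of (1 - 0.05)^2 ~ 0.90.
null_intercept_only_rate <- function() {
  mean(vapply(1:100, function(s) {
    set.seed(2000 + s)
    rec <- data.frame(y = stats::rnorm(50), x1 = stats::rnorm(50),
                      x2 = stats::rnorm(50))
    canopyvi::forward_stepwise(rec, "y", c("x1", "x2"),
                               alpha_enter = 0.05)$intercept_only
  }, logical(1)))
}
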