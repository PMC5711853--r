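# Synthetic canopy scenes and two-treatment trials.
#
# The generator emulates the structure of an early-growth maize phosphorus
# trial: 26 genotypes x 2 treatments (no phosphorus fertilizer, NPF, vs
# optimal phosphorus, OP; 52 plots), plot RGB images with a textured soil
# background and elliptical seedling canopies, pixel-aligned multispectral
# band stacks built from two endmember spectra (leaf vs soil), and a plot
# table whose yields and leaf traits follow treatment-dependent
# distributions with a planted canopy-cover -> yield linkage. Phosphorus
# deficiency is expressed as lower cover, chlorosis (hue shift toward
# yellow, flattened red-edge contrast in the bands) and purpling
# (darkening with a red/blue cast).
#
# Canopies are rendered as random elliptical blobs, not per-pixel noise, so
# that block-mean downsampling creates genuine plant/soil boundary mixed
# pixels.

# Endmember reflectance table over the 11 camera wavelengths. Healthy leaf
# has the classic low-red / high-NIR shape; full chlorosis raises red and
# lowers NIR monotonically; soil is a slowly rising featureless ramp.
.ENDMEMBERS <- data.frame(
  wavelength = SPECTRAL_WAVELENGTHS,
  leaf_healthy  = c(0.04, 0.12, 0.10, 0.04, 0.12, 0.30, 0.46, 0.48, 0.48, 0.47, 0.45),
  leaf_chlorotic = c(0.06, 0.16, 0.15, 0.14, 0.20, 0.30, 0.38, 0.38, 0.38, 0.37, 0.36),
  soil          = c(0.10, 0.16, 0.17, 0.22, 0.24, 0.25, 0.28, 0.30, 0.31, 0.32, 0.33)
)

#' Endmember reflectance for leaf or soil
#'
#' Declared piecewise endmember spectra over the supported wavelengths.
#' The leaf spectrum interpolates linearly between a healthy and a fully
#' chlorotic endpoint, so reflectance at 670 nm rises and at 840 nm falls
#' monotonically with chlorosis.
#'
#' @param wavelength Wavelength(s) in nm, from `SPECTRAL_WAVELENGTHS`.
#' @param material `"leaf"` or `"soil"`.
#' @param chlorosis Chlorosis severity in `[0, 1]` (leaf only).
#' @return Reflectance(s) in `[0, 1]`.
#' @export
leaf_soil_reflectance <- function(wavelength, material = c("leaf", "soil"),
                                  chlorosis = 0) {
  material <- match.arg(material)
  idx <- match(wavelength, .ENDMEMBERS$wavelength)
  if (anyNA(idx)) {
    stop(sprintf("unsupported wavelength(s): %s",
                 paste(wavelength[is.na(idx)], collapse = ", ")), call. = FALSE)
  }
  if (chlorosis < 0 || chlorosis > 1) stop("chlorosis must be in [0, 1]", call. = FALSE)
  if (material == "soil") return(.ENDMEMBERS$soil[idx])
  (1 - chlorosis) * .ENDMEMBERS$leaf_healthy[idx] +
    chlorosis * .ENDMEMBERS$leaf_chlorotic[idx]
}

#' Parameters for one synthetic canopy scene
#'
#' @param green_fraction Target canopy cover in `[0, 1]`.
#' @param chlorosis Hue shift of the canopy toward yellow, `[0, 1]`.
#' @param purpling Darkening with a red/blue cast (phosphorus-deficiency
#'   symptom), `[0, 1]`.
#' @param soil_color Mean soil RGB (8-bit).
#' @param leaf_hue_mean Mean leaf hue in degrees at zero chlorosis; full
#'   chlorosis shifts it down by `chlorosis_hue_shift`.
#' @param chlorosis_hue_shift Degrees of hue shift at chlorosis 1.
#' @param leaf_hue_sd Per-pixel hue scatter (degrees).
#' @param image_size `c(height, width)` in pixels, each >= 8.
#' @param seed Integer RNG seed for the scene.
#' @return A `scene_params` list.
#' @export
scene_params <- function(green_fraction = 0.15, chlorosis = 0.2, purpling = 0,
                         soil_color = c(120, 85, 60),
                         leaf_hue_mean = 115, chlorosis_hue_shift = 40,
                         leaf_hue_sd = 8,
                         image_size = c(128, 192), seed = 1L) {
  stopifnot(green_fraction >= 0, green_fraction <= 1,
            chlorosis >= 0, chlorosis <= 1, purpling >= 0, purpling <= 1,
            length(image_size) == 2L, all(image_size >= 8L),
            length(soil_color) == 3L)
  structure(list(green_fraction = green_fraction, chlorosis = chlorosis,
                 purpling = purpling, soil_color = soil_color,
                 leaf_hue_mean = leaf_hue_mean,
                 chlorosis_hue_shift = chlorosis_hue_shift,
                 leaf_hue_sd = leaf_hue_sd,
                 image_size = as.integer(image_size), seed = as.integer(seed)),
            class = "scene_params")
}

# Grow a canopy mask of elliptical blobs until the covered pixel count hits
# the target within +/- tol_px; the last blob is shrunk by bisection if it
# would overshoot.
.grow_canopy_mask <- function(h, w, target_px, tol_px) {
  canopy <- matrix(FALSE, h, w)
  if (target_px <= 0L) return(canopy)
  n <- h * w
  if (target_px >= n) return(matrix(TRUE, h, w))
  r0 <- max(2, round(min(h, w) / 14))
  rowg <- matrix(seq_len(h), h, w)
  colg <- matrix(seq_len(w), h, w, byrow = TRUE)
  blob <- function(cy, cx, ry, rx, th) {
    dy <- rowg - cy; dx <- colg - cx
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    (u / rx)^2 + (v / ry)^2 <= 1
  }
  it <- 0L
  while (sum(canopy) < target_px - tol_px && it < 10000L) {
    it <- it + 1L
    cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
    ry <- r0 * stats::runif(1, 0.5, 1.4); rx <- r0 * stats::runif(1, 0.5, 1.4)
    th <- stats::runif(1, 0, pi)
    cand <- canopy | blob(cy, cx, ry, rx, th)
    if (sum(cand) <= target_px + tol_px) {
      canopy <- cand
      next
    }
    # overshoot: bisect a scale factor for the last blob
    lo <- 0; hi <- 1; best <- canopy
    for (k in 1:12) {
      mid <- (lo + hi) / 2
      cand <- canopy | blob(cy, cx, max(0.5, ry * mid), max(0.5, rx * mid), th)
      if (sum(cand) > target_px + tol_px) hi <- mid
      else { lo <- mid; best <- cand }
    }
    canopy <- best
    if (sum(canopy) >= target_px - tol_px) break
  }
  canopy
}

# HSV -> 8-bit RGB, vectorised on equal-length h (degrees), s, v in [0,1].
.hsv_to_rgb255 <- function(h_deg, s, v) {
  h6 <- (h_deg %% 360) / 60
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b) * 255
}

#' Generate one synthetic canopy scene
#'
#' Renders a plot RGB image (textured soil background, elliptical green
#' canopy blobs) and a pixel-aligned multispectral band stack built from
#' the leaf/soil endmember spectra, together with ground-truth bookkeeping.
#' The realised canopy fraction is controlled to within about one pixel in
#' a hundred of the target for images of 128 x 128 and larger. Chlorosis
#' shifts leaf hue toward yellow and flattens the red-edge contrast of the
#' leaf spectrum; purpling darkens the canopy and blends it toward a
#' red/blue cast.
#'
#' @param params A [scene_params()] object.
#' @return A list with elements `rgb` ([rgb_image()]), `stack`
#'   ([band_stack()]) and `truth` (list: `true_green_fraction`,
#'   `true_gga_fraction`, `n_canopy`, `n_soil`, `n_pixels`).
#' @export
generate_canopy_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  h <- params$image_size[1L]; w <- params$image_size[2L]
  n <- h * w
  target_px <- round(params$green_fraction * n)
  tol_px <- max(1L, floor(0.005 * n))
  canopy <- .grow_canopy_mask(h, w, target_px, tol_px)
  k <- sum(canopy)

  # soil background: multiplicative brightness texture plus channel jitter
  bright <- pmin(1.6, pmax(0.4, 1 + stats::rnorm(n, 0, 0.12)))
  px <- matrix(0, n, 3L)
  for (c3 in 1:3) {
    px[, c3] <- pmin(255, pmax(0, params$soil_color[c3] * bright +
                                 stats::rnorm(n, 0, 4)))
  }

  hue_drawn <- numeric(0)
  if (k > 0L) {
    hue <- stats::rnorm(k, params$leaf_hue_mean -
                          params$chlorosis_hue_shift * params$chlorosis,
                        params$leaf_hue_sd)
    hue <- pmin(175, pmax(65, hue))
    sat <- pmin(0.9, pmax(0.3, stats::rnorm(k, 0.55, 0.08)))
    val <- pmin(0.95, pmax(0.15,
            stats::rnorm(k, 0.55, 0.08) * (1 - 0.35 * params$purpling)))
    leaf_rgb <- .hsv_to_rgb255(hue, sat, val)
    # purpling: mild blend toward a dark red/blue cast
    wgt <- 0.18 * params$purpling
    leaf_rgb <- (1 - wgt) * leaf_rgb +
      wgt * matrix(c(90, 50, 110), k, 3L, byrow = TRUE)
    px[as.vector(canopy), ] <- pmin(255, pmax(0, leaf_rgb))
    hue_drawn <- hue
  }
  pixels <- array(as.integer(round(px)), dim = c(h, w, 3L))
  img <- rgb_image(pixels, platform = "ground")

  # band stack from endmember spectra with mild multiplicative noise
  bands <- vector("list", length(SPECTRAL_WAVELENGTHS))
  names(bands) <- as.character(SPECTRAL_WAVELENGTHS)
  cv <- as.vector(canopy)
  for (i in seq_along(SPECTRAL_WAVELENGTHS)) {
    wl <- SPECTRAL_WAVELENGTHS[i]
    base <- ifelse(cv, leaf_soil_reflectance(wl, "leaf", params$chlorosis),
                   leaf_soil_reflectance(wl, "soil"))
    bands[[i]] <- matrix(pmin(1, pmax(0, base * (1 + stats::rnorm(n, 0, 0.03)))),
                         h, w)
  }

  truth <- list(
    true_green_fraction = k / n,
    true_gga_fraction = if (k > 0L) sum(hue_drawn >= 80 & hue_drawn <= 180) / n else 0,
    n_canopy = k, n_soil = n - k, n_pixels = n
  )
  list(rgb = img, stack = band_stack(bands), truth = truth)
}

#' Design of a synthetic two-treatment trial
#'
#' Defaults reproduce the structure of the emulated study: 26 genotypes in
#' two phosphorus arms (52 plots), treatment mean yields 5.64 (NPF) and
#' 7.50 (OP) t/ha, mean canopy cover 0.08 vs 0.21, and leaf traits centred
#' on the study's treatment means. Yields are drawn as treatment mean +
#' shared genotype effect + cover-linked term + residual; leaf phosphorus
#' is partially linked to cover within each arm.
#'
#' @param n_genotypes Number of genotypes (plots = 2 x this).
#' @param mean_yield Named per-treatment mean grain yield, t/ha.
#' @param genotype_sd,residual_sd Yield components, t/ha.
#' @param cover_mean,cover_sd Named per-treatment canopy-cover distributions.
#' @param cover_yield_slope Yield change per unit canopy cover, t/ha.
#' @param chlorosis,purpling Named per-treatment symptom severities.
#' @param trait_means,trait_sds Named lists of per-treatment leaf-trait
#'   means/SDs (leaf P mg/g, LCC, N %, C %, C/N, d13C and d15N per mil).
#' @param image_size Scene size `c(height, width)` for rendered plots.
#' @param seed Integer master seed; plot i uses scene seed `seed + i`.
#' @return A `trial_design` list.
#' @export
trial_design <- function(n_genotypes = 26L,
                         mean_yield = c(NPF = 5.64, OP = 7.50),
                         genotype_sd = 0.40, residual_sd = 0.42,
                         cover_mean = c(NPF = 0.08, OP = 0.21),
                         cover_sd = c(NPF = 0.05, OP = 0.05),
                         cover_yield_slope = 16.5,
                         chlorosis = c(NPF = 0.5, OP = 0.1),
                         purpling = c(NPF = 0.3, OP = 0.05),
                         trait_means = list(
                           leaf_p = c(NPF = 2.06, OP = 4.81),
                           lcc = c(NPF = 32.01, OP = 46.19),
                           n_pct = c(NPF = 3.95, OP = 4.30),
                           c_pct = c(NPF = 43.62, OP = 43.03),
                           cn_ratio = c(NPF = 11.08, OP = 10.06),
                           d13c = c(NPF = -11.66, OP = -11.61),
                           d15n = c(NPF = -1.32, OP = -1.09)),
                         trait_sds = list(
                           leaf_p = c(NPF = 0.41, OP = 0.56),
                           lcc = c(NPF = 5.05, OP = 3.98),
                           n_pct = c(NPF = 0.20, OP = 0.31),
                           c_pct = c(NPF = 0.51, OP = 1.17),
                           cn_ratio = c(NPF = 0.56, OP = 0.66),
                           d13c = c(NPF = 0.15, OP = 0.20),
                           d15n = c(NPF = 1.17, OP = 1.53)),
                         image_size = c(128, 192),
                         seed = 1L) {
  stopifnot(n_genotypes >= 2L, genotype_sd >= 0, residual_sd >= 0,
            all(cover_sd >= 0), all(c("NPF", "OP") %in% names(mean_yield)))
  structure(list(n_genotypes = as.integer(n_genotypes),
                 treatments = c("NPF", "OP"),
                 mean_yield = mean_yield, genotype_sd = genotype_sd,
                 residual_sd = residual_sd, cover_mean = cover_mean,
                 cover_sd = cover_sd, cover_yield_slope = cover_yield_slope,
                 chlorosis = chlorosis, purpling = purpling,
                 trait_means = trait_means, trait_sds = trait_sds,
                 image_size = as.integer(image_size), seed = as.integer(seed)),
            class = "trial_design")
}

#' Planted canopy-cover/yield correlation of a trial design
#'
#' Closed-form Pearson correlation between true canopy cover and grain
#' yield over the pooled (both-arm, balanced) sample implied by a
#' [trial_design()]: within-arm covariance comes from the cover-yield
#' slope, between-arm covariance from the separation of the treatment
#' means. Used as the reference value in parameter-recovery checks.
#'
#' @param design A [trial_design()].
#' @return The expected pooled Pearson correlation.
#' @export
planted_cover_yield_correlation <- function(design) {
  b <- design$cover_yield_slope
  vc_w <- mean(design$cover_sd^2)
  vy_w <- mean((b * design$cover_sd)^2) + design$genotype_sd^2 + design$residual_sd^2
  cov_w <- b * vc_w
  dc <- diff(design$cover_mean[c("NPF", "OP")])
  dy <- diff(design$mean_yield[c("NPF", "OP")])
  num <- cov_w + dc * dy / 4
  den <- sqrt((vc_w + dc^2 / 4) * (vy_w + dy^2 / 4))
  unname(num / den)
}

#' Generate a synthetic two-treatment trial
#'
#' Draws the plot table (yields, leaf traits, per-plot cover and symptom
#' severities) from the design and, when `render = TRUE`, renders each
#' plot's RGB scene and band stack with a per-plot seed (`seed + plot
#' index`) so any single plot is reproducible in isolation.
#'
#' @param design A [trial_design()].
#' @param render Render per-plot scenes (set `FALSE` for table-only use in
#'   statistical simulations).
#' @return A list with `records` (data.frame, one row per plot: plot_id,
#'   genotype, treatment, grain_yield, leaf traits, true_cover, chlorosis,
#'   purpling, scene_seed) and `scenes` (named list of
#'   [generate_canopy_scene()] outputs, or `NULL`).
#' @export
generate_trial <- function(design = trial_design(), render = TRUE) {
  stopifnot(inherits(design, "trial_design"))
  set.seed(design$seed)
  ng <- design$n_genotypes
  geno <- sprintf("G%02d", seq_len(ng))
  g_eff <- stats::rnorm(ng, 0, design$genotype_sd)

  rec <- expand.grid(genotype = geno, treatment = design$treatments,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nr <- nrow(rec)
  rec$plot_id <- sprintf("%s_%s", rec$treatment, rec$genotype)
  trt <- rec$treatment

  cover <- stats::rnorm(nr, design$cover_mean[trt], design$cover_sd[trt])
  cover <- pmin(0.95, pmax(0.01, cover))
  resid <- stats::rnorm(nr, 0, design$residual_sd)
  rec$grain_yield <- pmax(0, design$mean_yield[trt] +
    g_eff[match(rec$genotype, geno)] +
    design$cover_yield_slope * (cover - design$cover_mean[trt]) + resid)

  z_cover <- (cover - design$cover_mean[trt]) /
    pmax(design$cover_sd[trt], 1e-12)
  for (trait in names(design$trait_means)) {
    mu <- design$trait_means[[trait]][trt]
    sd <- design$trait_sds[[trait]][trt]
    link <- if (trait %in% c("leaf_p", "lcc", "n_pct")) 0.6 else 0
    rec[[trait]] <- mu + sd * (link * z_cover +
                                 sqrt(1 - link^2) * stats::rnorm(nr))
  }
  rec$true_cover <- cover
  rec$chlorosis <- pmin(1, pmax(0, design$chlorosis[trt] +
                                  0.1 * stats::rnorm(nr)))
  rec$purpling <- pmin(1, pmax(0, design$purpling[trt] + 0.05 * stats::rnorm(nr)))
  rec$scene_seed <- design$seed + seq_len(nr)
  rec <- rec[, c("plot_id", "genotype", "treatment", "grain_yield",
                 names(design$trait_means), "true_cover", "chlorosis",
                 "purpling", "scene_seed")]

  scenes <- NULL
  if (render) {
    scenes <- vector("list", nr)
    names(scenes) <- rec$plot_id
    for (i in seq_len(nr)) {
      scenes[[i]] <- generate_canopy_scene(scene_params(
        green_fraction = rec$true_cover[i],
        chlorosis = rec$chlorosis[i], purpling = rec$purpling[i],
        image_size = design$image_size, seed = rec$scene_seed[i]))
    }
  }
  list(records = rec, scenes = scenes, design = design)
}

#' Assemble a trial's plot scenes into one mosaic with a plot grid
#'
#' Lays the rendered plots out row-major on a rectangular grid and returns
#' the mosaic image together with the [plot_grid()] that crops it back into
#' the individual plots.
#'
#' @param trial Output of [generate_trial()] with rendered scenes.
#' @param ncol Number of plots per mosaic row.
#' @return A list with `mosaic` ([rgb_image()]) and `grid` ([plot_grid()]).
#' @export
trial_mosaic <- function(trial, ncol = 13L) {
  stopifnot(!is.null(trial$scenes))
  n <- length(trial$scenes)
  nrow_m <- ceiling(n / ncol)
  d <- dim(trial$scenes[[1L]]$rgb$pixels)
  big <- array(0L, dim = c(nrow_m * d[1L], ncol * d[2L], 3L))
  ids <- names(trial$scenes)
  r0 <- integer(n); c0 <- integer(n)
  for (i in seq_len(n)) {
    ri <- (i - 1L) %/% ncol; ci <- (i - 1L) %% ncol
    r0[i] <- ri * d[1L]; c0[i] <- ci * d[2L]
    big[r0[i] + seq_len(d[1L]), c0[i] + seq_len(d[2L]), ] <-
      trial$scenes[[i]]$rgb$pixels
  }
  list(mosaic = rgb_image(big, plot_id = "mosaic"),
       grid = plot_grid(ids, r0, c0, d[1L], d[2L]))
}
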