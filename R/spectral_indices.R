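# Multispectral vegetation indices from narrow-band reflectance.
#
# The supported band set is the 11 camera channels, keyed by centre
# wavelength in nm. Each index is computed exactly from its published
# formula; denominators that vanish yield NA (an explicit undefined-value
# sentinel) rather than an infinity.

#' Wavelengths (nm) of the supported multispectral band set
#' @export
SPECTRAL_WAVELENGTHS <- c(450, 550, 570, 670, 700, 720, 780, 840, 860, 900, 950)

#' Names of the twelve plot-level spectral indices
#' @export
SPECTRAL_INDEX_NAMES <- c(
  "ndvi", "savi", "osavi", "rdvi", "evi", "pri",
  "mcari", "tcari", "tcari_osavi", "ari2", "cri2", "wbi"
)

.band <- function(bands, wl) {
  key <- as.character(wl)
  if (!key %in% names(bands)) {
    stop(sprintf("band %s nm required but not present", key), call. = FALSE)
  }
  bands[[key]]
}

.guard_div <- function(num, den) {
  out <- ifelse(abs(den) < .Machine$double.xmin, NA_real_, num / den)
  as.numeric(out)
}

#' Compute one spectral vegetation index from band reflectances
#'
#' Evaluates the published formula for the named index on a set of band
#' reflectances keyed by centre wavelength (nm). Works elementwise, so the
#' band values may be scalars (plot means) or equally shaped arrays
#' (per-pixel maps).
#'
#' Available indices: `ndvi`, `savi` (soil factor `L`; 1 for low, 0.5 for
#' intermediate, 0.25 for high vegetation cover), `osavi`, `rdvi`, `evi`,
#' `pri`, `mcari`, `tcari`, `tcari_osavi` (the TCARI/OSAVI ratio), `ari2`,
#' `cri2` and `wbi`.
#'
#' The TCARI source string is parenthesis-ambiguous; the default follows the
#' canonical form `3 * ((B700 - B670) - 0.2 * (B700 - B550) * (B700/B670))`.
#' Set `literal = TRUE` for the alternative reading
#' `3 * (B700 - B670) - 0.2 * (B700 - B550) * (B700/B670)`. The `wbi`
#' implemented here is the red/NIR form used with this camera's band set
#' (algebraically the same shape as RDVI); see [wbi_ratio()] for a
#' conventional NIR ratio-form water band index.
#'
#' @param name Index identifier (case-insensitive), one of
#'   `SPECTRAL_INDEX_NAMES`.
#' @param bands Named list or vector of reflectances in `[0, 1]`, names are
#'   wavelengths in nm (e.g. `c("670" = 0.05, "840" = 0.45)`).
#' @param L Soil-adjustment factor for SAVI (default 0.5, "intermediate").
#' @param literal Use the literal parse of the TCARI source string.
#' @return The index value(s); `NA` where a denominator vanishes.
#' @examples
#' spectral_index("ndvi", c("670" = 0.1, "840" = 0.5)) # 0.4 / 0.6
#' @export
spectral_index <- function(name, bands, L = 0.5, literal = FALSE) {
  name <- tolower(name)
  if (!is.list(bands)) bands <- as.list(bands)
  B <- function(wl) .band(bands, wl)
  switch(name,
    ndvi = .guard_div(B(840) - B(670), B(840) + B(670)),
    savi = .guard_div((B(840) - B(670)) * (1 + L), B(840) + B(670) + L),
    osavi = .guard_div((1 + 0.16) * (B(780) - B(670)), B(780) + B(670) + 0.16),
    rdvi = .guard_div(B(840) - B(670), sqrt(B(840) + B(670))),
    evi = .guard_div(2.5 * (B(840) - B(670)),
                     B(840) + 6 * B(670) - 7.5 * B(450) + 1),
    pri = .guard_div(B(550) - B(570), B(550) + B(570)),
    mcari = as.numeric(((B(700) - B(670)) - 0.2 * (B(700) - B(550))) *
                         .guard_div(B(700), B(670))),
    tcari = {
      ratio <- .guard_div(B(700), B(670))
      if (literal) {
        as.numeric(3 * (B(700) - B(670)) - 0.2 * (B(700) - B(550)) * ratio)
      } else {
        as.numeric(3 * ((B(700) - B(670)) - 0.2 * (B(700) - B(550)) * ratio))
      }
    },
    tcari_osavi = .guard_div(
      spectral_index("tcari", bands, L = L, literal = literal),
      spectral_index("osavi", bands, L = L)
    ),
    ari2 = as.numeric(B(840) * (.guard_div(1, B(550)) - .guard_div(1, B(700)))),
    cri2 = as.numeric(.guard_div(1, B(550)) - .guard_div(1, B(700))),
    wbi = .guard_div(B(840) - B(670), sqrt(B(840) + B(670))),
    stop(sprintf("unknown spectral index '%s'", name), call. = FALSE)
  )
}

#' Ratio-form water band index from the NIR bands
#'
#' The conventional water band index is the ratio of a reference NIR band to
#' a water-absorption band near 970 nm. This camera's band set stops at
#' 950 nm, so the ratio is formed from the two available NIR channels,
#' `B900 / B950`. Provided separately from [spectral_index()]'s `wbi`, which
#' follows the red/NIR form used with this band set.
#'
#' @inheritParams spectral_index
#' @return The `B900 / B950` ratio; `NA` where `B950` vanishes.
#' @export
wbi_ratio <- function(bands) {
  if (!is.list(bands)) bands <- as.list(bands)
  .guard_div(.band(bands, 900), .band(bands, 950))
}

#' Construct a multispectral band stack
#'
#' A band stack is a set of co-registered 2-D reflectance maps keyed by
#' centre wavelength (nm), all of the same shape, with reflectances in
#' `[0, 1]`, plus an optional logical mask of valid pixels.
#'
#' @param bands Named list of numeric matrices; names are wavelengths in nm
#'   drawn from `SPECTRAL_WAVELENGTHS`.
#' @param mask Optional logical matrix, same shape as the bands.
#' @param plot_id Optional plot identifier carried through summaries.
#' @return An object of class `band_stack`.
#' @export
band_stack <- function(bands, mask = NULL, plot_id = NA_character_) {
  if (length(bands) == 0L) stop("band stack needs at least one band", call. = FALSE)
  if (is.null(names(bands)) || anyNA(names(bands)) || any(names(bands) == "")) {
    stop("bands must be named by wavelength (nm)", call. = FALSE)
  }
  if (anyDuplicated(names(bands))) stop("duplicate wavelengths", call. = FALSE)
  wl <- suppressWarnings(as.numeric(names(bands)))
  if (anyNA(wl)) stop("band names must be numeric wavelengths", call. = FALSE)
  unknown <- setdiff(wl, SPECTRAL_WAVELENGTHS)
  if (length(unknown)) {
    stop(sprintf("unsupported wavelength(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  bands <- lapply(bands, as.matrix)
  shp <- dim(bands[[1L]])
  for (b in bands) {
    if (!identical(dim(b), shp)) stop("all bands must share one shape", call. = FALSE)
    if (anyNA(b) || any(b < 0) || any(b > 1)) {
      stop("reflectances must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(mask) && !identical(dim(as.matrix(mask)), shp)) {
    stop("mask shape must match band shape", call. = FALSE)
  }
  structure(list(bands = bands, mask = mask, plot_id = plot_id),
            class = "band_stack")
}

#' @export
print.band_stack <- function(x, ...) {
  shp <- dim(x$bands[[1L]])
  cat(sprintf("band_stack: %d bands (%s nm), %d x %d px, plot %s\n",
              length(x$bands), paste(names(x$bands), collapse = "/"),
              shp[1L], shp[2L], x$plot_id))
  invisible(x)
}

#' Summarise a plot's band stack into spectral indices and band means
#'
#' In `mean-reflectance` mode (the default, matching plot-level reporting)
#' each index is the formula applied to the plot-mean reflectance of each
#' band. In `per-pixel-mean` mode each index is computed per pixel and then
#' averaged over valid (unmasked, defined) pixels; the two modes agree
#' exactly on spatially uniform stacks.
#'
#' @param stack A [band_stack()].
#' @param mode `"mean-reflectance"` or `"per-pixel-mean"`.
#' @param L SAVI soil-adjustment factor.
#' @return A one-row data.frame with the twelve indices, one `b<wl>` column
#'   of mean reflectance per band, `savi_L`, `mode` and `n_undefined` (count
#'   of per-pixel index values that hit a vanishing denominator).
#' @export
summarize_spectral_plot <- function(stack,
                                    mode = c("mean-reflectance", "per-pixel-mean"),
                                    L = 0.5) {
  stopifnot(inherits(stack, "band_stack"))
  mode <- match.arg(mode)
  keep <- if (is.null(stack$mask)) TRUE else as.vector(stack$mask)
  vals <- lapply(stack$bands, function(b) as.vector(b)[keep])
  if (length(vals[[1L]]) == 0L) stop("mask selects no pixels", call. = FALSE)
  band_means <- vapply(vals, mean, numeric(1))

  # indices whose bands the stack lacks are reported NA, not errors
  try_index <- function(expr) {
    tryCatch(expr, error = function(e) {
      if (grepl("required but not present", conditionMessage(e))) NA_real_
      else stop(e)
    })
  }
  n_undef <- 0L
  if (mode == "mean-reflectance") {
    idx <- vapply(SPECTRAL_INDEX_NAMES, function(nm) {
      try_index(spectral_index(nm, as.list(band_means), L = L))
    }, numeric(1))
  } else {
    idx <- vapply(SPECTRAL_INDEX_NAMES, function(nm) {
      per_px <- try_index(spectral_index(nm, vals, L = L))
      if (length(per_px) == 1L && all(is.na(per_px))) return(NA_real_)
      n_undef <<- n_undef + sum(is.na(per_px))
      mean(per_px, na.rm = TRUE)
    }, numeric(1))
  }
  out <- as.data.frame(as.list(idx))
  names(out) <- SPECTRAL_INDEX_NAMES
  bm <- as.data.frame(as.list(band_means))
  names(bm) <- paste0("b", names(stack$bands))
  cbind(plot_id = stack$plot_id, out, bm,
        savi_L = L, mode = mode, n_undefined = n_undef,
        stringsAsFactors = FALSE)
}
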