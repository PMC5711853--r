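# Image and table I/O, plot cropping, and aerial-resolution emulation.
#
# Images are stored as h x w x 3 integer arrays of 8-bit values with a plot
# id and a platform tag ("ground" or "aerial"). Multispectral stacks are
# read as one single-page TIFF per band plus a plain-text manifest mapping
# wavelength (nm) to filename. Coordinates are 0-based, row-major, and crop
# rectangles are half-open.

#' Default ground-to-aerial downsampling factor
#'
#' Chosen so that a ground plot image (4608 x 3072 px, 14.2 Mpx) is reduced
#' to the per-plot pixel count of the aerial platform (488 x 193 px,
#' 0.094 Mpx): the linear ratio is sqrt(14.16/0.094) = 12.3, rounded to the
#' nearest integer block size. The two printed axes have different ratios
#' (9.4 and 15.9) because the two platforms' crops are not geometrically
#' similar, so pixel count is the quantity matched.
#' @export
AERIAL_DOWNSAMPLE_FACTOR <- 12L

#' Construct a plot RGB image
#'
#' @param pixels h x w x 3 array of 8-bit channel values (0-255).
#' @param plot_id Plot identifier.
#' @param platform Acquisition platform tag, `"ground"` or `"aerial"`.
#' @return An object of class `rgb_image` with fields `pixels`, `plot_id`,
#'   `platform`.
#' @export
rgb_image <- function(pixels, plot_id = NA_character_, platform = c("ground", "aerial")) {
  platform <- match.arg(platform)
  if (length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L) {
    stop("pixels must be an h x w x 3 array", call. = FALSE)
  }
  if (any(dim(pixels)[1:2] < 1L)) stop("image must be non-empty", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255)) {
    stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, plot_id = plot_id, platform = platform),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("rgb_image: %d x %d px, platform %s, plot %s\n",
              d[1L], d[2L], x$platform, x$plot_id))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

#' Read a plot RGB image from PNG or TIFF
#'
#' Decodes to an 8-bit, 3-channel [rgb_image()]. Greyscale images are
#' promoted to 3 channels by replication (with a warning); an alpha channel
#' is dropped; higher bit depths are rescaled to 8-bit (with a message).
#' JPEG is not supported by the installed decoders.
#'
#' @param path File path (`.png`, `.tif`/`.tiff`).
#' @inheritParams rgb_image
#' @return An [rgb_image()].
#' @export
read_rgb_image <- function(path, plot_id = NA_character_,
                           platform = c("ground", "aerial")) {
  platform <- match.arg(platform)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path, info = TRUE),
    tif = ,
    tiff = tiff::readTIFF(path, info = TRUE),
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF expected)", ext),
         call. = FALSE)
  )
  info <- attr(raw, "info")                      # png attaches a list ...
  depth <- if (!is.null(info$bit.depth)) info$bit.depth
    else if (!is.null(attr(raw, "bits.per.sample")))
      attr(raw, "bits.per.sample")               # ... tiff, flat attributes
    else 8L
  if (any(depth > 8L)) {
    message(sprintf("%s: %d-bit samples rescaled to 8-bit", basename(path),
                    max(depth)))
  }
  if (length(dim(raw)) == 2L) {
    warning(sprintf("%s: greyscale image promoted to 3 channels", basename(path)))
    raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  }
  nc <- dim(raw)[3L]
  if (nc == 4L) raw <- raw[, , 1:3, drop = FALSE]
  else if (nc == 2L) {
    warning(sprintf("%s: greyscale image promoted to 3 channels", basename(path)))
    raw <- array(rep(raw[, , 1L], 3L), dim = c(dim(raw)[1:2], 3L))
  } else if (nc != 3L) {
    stop(sprintf("%s: unsupported channel count %d", basename(path), nc),
         call. = FALSE)
  }
  px <- array(as.integer(round(raw * 255)), dim = dim(raw))
  rgb_image(px, plot_id = plot_id, platform = platform)
}

#' Write a plot RGB image to PNG or TIFF
#'
#' @param image An [rgb_image()].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  norm <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(norm, path),
    tif = ,
    tiff = tiff::writeTIFF(norm, path, bits.per.sample = 8L),
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
  )
  invisible(path)
}

#' Define a grid of plot regions on a mosaic
#'
#' Regions are 0-based, row-major, half-open rectangles: a region covers
#' rows `row0 .. row0 + height - 1` and columns `col0 .. col0 + width - 1`.
#'
#' @param plot_id Character vector of unique plot ids.
#' @param row0,col0 0-based origins of each region.
#' @param height,width Region sizes in pixels (>= 1).
#' @return A `plot_grid` data.frame.
#' @export
plot_grid <- function(plot_id, row0, col0, height, width) {
  g <- data.frame(plot_id = as.character(plot_id), row0 = as.integer(row0),
                  col0 = as.integer(col0), height = as.integer(height),
                  width = as.integer(width), stringsAsFactors = FALSE)
  if (anyDuplicated(g$plot_id)) stop("plot ids must be unique", call. = FALSE)
  if (any(g$row0 < 0L | g$col0 < 0L)) stop("origins must be >= 0", call. = FALSE)
  if (any(g$height < 1L | g$width < 1L)) stop("regions must be non-empty", call. = FALSE)
  class(g) <- c("plot_grid", "data.frame")
  g
}

#' Crop per-plot images or stacks from a mosaic
#'
#' @param mosaic An [rgb_image()] or [band_stack()] covering the whole trial.
#' @param grid A [plot_grid()]; every region must lie within the mosaic.
#' @return A named list (by plot id) of per-plot objects of the same class
#'   as the mosaic, pixel-exact sub-regions.
#' @export
crop_plot_grid <- function(mosaic, grid) {
  stopifnot(inherits(grid, "plot_grid"))
  shp <- if (inherits(mosaic, "rgb_image")) dim(mosaic$pixels)[1:2]
         else if (inherits(mosaic, "band_stack")) dim(mosaic$bands[[1L]])
         else stop("mosaic must be an rgb_image or band_stack", call. = FALSE)
  out <- vector("list", nrow(grid))
  names(out) <- grid$plot_id
  for (i in seq_len(nrow(grid))) {
    r <- grid[i, ]
    if (r$row0 + r$height > shp[1L] || r$col0 + r$width > shp[2L]) {
      stop(sprintf("plot '%s': region exceeds mosaic bounds", r$plot_id),
           call. = FALSE)
    }
    rows <- (r$row0 + 1L):(r$row0 + r$height)
    cols <- (r$col0 + 1L):(r$col0 + r$width)
    out[[i]] <- if (inherits(mosaic, "rgb_image")) {
      rgb_image(mosaic$pixels[rows, cols, , drop = FALSE],
                plot_id = r$plot_id, platform = mosaic$platform)
    } else {
      band_stack(lapply(mosaic$bands, function(b) b[rows, cols, drop = FALSE]),
                 mask = if (is.null(mosaic$mask)) NULL
                        else mosaic$mask[rows, cols, drop = FALSE],
                 plot_id = r$plot_id)
    }
  }
  out
}

# Block-mean reduction of one matrix by integer factor f, cropping to the
# largest multiple of f first.
.block_mean <- function(m, f) {
  h <- nrow(m); w <- ncol(m)
  h2 <- f * (h %/% f); w2 <- f * (w %/% f)
  if (h2 < f || w2 < f) stop("factor larger than image", call. = FALSE)
  m <- m[seq_len(h2), seq_len(w2), drop = FALSE]
  a <- colMeans(array(m, c(f, h2 %/% f, w2)))        # rows within blocks
  t(colMeans(array(t(a), c(f, w2 %/% f, h2 %/% f)))) # cols within blocks
}

#' Degrade a ground image to emulate aerial resolution
#'
#' Reduces spatial resolution by block-mean downsampling with an integer
#' factor: every output pixel is the mean of an f x f block, so boundary
#' pixels between canopy and soil become genuine mixed pixels — the
#' mechanism by which coarser aerial imagery blurs the plant/soil boundary.
#' The image is first cropped to the largest multiple of the factor; the
#' platform tag of the result is `"aerial"`. Factor 1 returns the image
#' unchanged (apart from the tag).
#'
#' @param image An [rgb_image()].
#' @param factor Positive integer block size (default
#'   [AERIAL_DOWNSAMPLE_FACTOR]).
#' @return An [rgb_image()] with platform `"aerial"`.
#' @export
degrade_resolution <- function(image, factor = AERIAL_DOWNSAMPLE_FACTOR) {
  stopifnot(inherits(image, "rgb_image"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be >= 1", call. = FALSE)
  if (factor == 1L) {
    return(rgb_image(image$pixels, plot_id = image$plot_id, platform = "aerial"))
  }
  ch <- lapply(1:3, function(k) .block_mean(image$pixels[, , k], factor))
  px <- array(as.integer(round(ch[[1L]])), dim = c(dim(ch[[1L]]), 3L))
  px[, , 2L] <- as.integer(round(ch[[2L]]))
  px[, , 3L] <- as.integer(round(ch[[3L]]))
  rgb_image(px, plot_id = image$plot_id, platform = "aerial")
}

#' Write a plot index table to CSV
#'
#' Comma-separated, UTF-8, "." decimal, mandatory header; numeric values
#' are written with 6 significant digits and undefined values (NA) as empty
#' cells. The number of empty (undefined) numeric cells is reported with a
#' message.
#'
#' @param records A data.frame of per-plot records sharing one schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  n_na <- 0L
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      n_na <- n_na + sum(is.na(out[[j]]))
      out[[j]] <- signif(out[[j]], 6)
    }
  }
  if (n_na > 0L) message(sprintf("%d undefined value(s) written as empty cells", n_na))
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a plot index table written by [write_index_table()]
#' @param path CSV path.
#' @return A data.frame; empty cells become NA.
#' @export
read_index_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  fileEncoding = "UTF-8")
}

#' Write a band stack as per-band TIFFs plus a manifest
#'
#' One single-page float TIFF per band, named `<prefix>_<wavelength>.tif`,
#' plus a plain-text manifest CSV with columns `wavelength_nm,filename`.
#'
#' @param stack A [band_stack()].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix, default the plot id.
#' @return The manifest path, invisibly.
#' @export
write_band_stack <- function(stack, dir, prefix = NULL) {
  stopifnot(inherits(stack, "band_stack"))
  if (is.null(prefix)) prefix <- if (is.na(stack$plot_id)) "stack" else stack$plot_id
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(stack$bands))
  for (i in seq_along(stack$bands)) {
    files[i] <- sprintf("%s_%s.tif", prefix, names(stack$bands)[i])
    tiff::writeTIFF(stack$bands[[i]], file.path(dir, files[i]),
                    bits.per.sample = 32L)
  }
  manifest <- file.path(dir, sprintf("%s_manifest.csv", prefix))
  utils::write.csv(
    data.frame(wavelength_nm = names(stack$bands), filename = files),
    manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a band stack from a manifest of per-band TIFFs
#'
#' @param manifest Path to a CSV with columns `wavelength_nm,filename`
#'   (filenames relative to the manifest's directory).
#' @param plot_id Optional plot id for the stack.
#' @return A [band_stack()].
#' @export
read_band_stack <- function(manifest, plot_id = NA_character_) {
  if (!file.exists(manifest)) stop(sprintf("no such file: %s", manifest), call. = FALSE)
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("wavelength_nm", "filename") %in% names(tab))) {
    stop("manifest needs columns wavelength_nm, filename", call. = FALSE)
  }
  base <- dirname(manifest)
  bands <- lapply(tab$filename, function(f) {
    m <- tiff::readTIFF(file.path(base, f))
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    m
  })
  names(bands) <- as.character(tab$wavelength_nm)
  band_stack(bands, plot_id = plot_id)
}
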