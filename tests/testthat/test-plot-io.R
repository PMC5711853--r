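# Image/table I/O, plot cropping, aerial-resolution emulation.

test_that("PNG and TIFF round-trip pixel-exactly", {
  px <- array(as.integer(c(0, 255, 17, 101, 30, 60, 240, 5, 9, 77, 128, 200)),
              dim = c(2, 2, 3))
  img <- rgb_image(px, plot_id = "p1")
  for (ext in c("png", "tif")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_rgb_image(img, path)
    back <- read_rgb_image(path, plot_id = "p1")
    expect_identical(back$pixels, px)
  }
})

test_that("16-bit TIFF is rescaled to 8-bit with a note", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(c(0, 0.5, 1, 0.25), dim = c(2, 2, 1))[, , c(1, 1, 1)],
                  path, bits.per.sample = 16L)
  expect_message(img <- read_rgb_image(path), "16-bit")
  # 16-bit quantisation can shift half-integer values by one 8-bit step
  expect_true(all(abs(img$pixels[, , 1] -
                        matrix(c(0, 0.5, 1, 0.25) * 255, 2, 2)) <= 1))
})

test_that("greyscale is promoted with a warning; truncated files error", {
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(c(0, 0.2, 0.8, 1), 2, 2), path)
  expect_warning(img <- read_rgb_image(path), "greyscale")
  expect_equal(img$pixels[, , 1], img$pixels[, , 3])

  bad <- withr::local_tempfile(fileext = ".png")
  writeBin(charToRaw("this is not a png"), bad)
  expect_error(read_rgb_image(bad))
  expect_error(read_rgb_image("does/not/exist.png"), "no such file")
  jpg <- withr::local_tempfile(fileext = ".jpg")
  writeBin(raw(4), jpg)
  expect_error(read_rgb_image(jpg), "unsupported image format")
})

test_that("cropping is pixel-exact, conserving, and bounds-checked", {
  set.seed(41)
  mosaic <- rgb_image(random_rgb_image(20, 30), plot_id = "m")
  # single region equal to the whole mosaic
  whole <- crop_plot_grid(mosaic, plot_grid("all", 0, 0, 20, 30))
  expect_identical(whole$all$pixels, mosaic$pixels)
  # two disjoint regions conserve pixel sums
  g <- plot_grid(c("a", "b"), c(0, 10), c(0, 0), c(10, 10), c(30, 30))
  crops <- crop_plot_grid(mosaic, g)
  expect_identical(sum(crops$a$pixels) + sum(crops$b$pixels),
                   sum(mosaic$pixels))
  # out-of-bounds names the plot id
  expect_error(crop_plot_grid(mosaic, plot_grid("far", 15, 0, 10, 10)), "far")
})

test_that("a full synthetic trial mosaic crops back into 52 plots", {
  tr <- generate_trial(trial_design(image_size = c(24, 32), seed = 3))
  tm <- trial_mosaic(tr)
  crops <- crop_plot_grid(tm$mosaic, tm$grid)
  expect_length(crops, 52)
  expect_identical(crops[[7]]$pixels, tr$scenes[[7]]$rgb$pixels)
})

test_that("degrade_resolution: identity at factor 1, block means, conservation", {
  set.seed(42)
  img <- rgb_image(random_rgb_image(16, 24))
  same <- degrade_resolution(img, 1)
  expect_identical(same$pixels, img$pixels)
  expect_equal(same$platform, "aerial")

  d <- degrade_resolution(img, 8)
  expect_equal(dim(d$pixels)[1:2], c(2, 3))
  # non-divisible dimensions crop to the largest multiple
  d2 <- degrade_resolution(rgb_image(random_rgb_image(18, 27)), 8)
  expect_equal(dim(d2$pixels)[1:2], c(2, 3))
  # mean colour preserved to 8-bit rounding when factor divides dims
  for (k in 1:3) {
    expect_lte(abs(mean(img$pixels[, , k]) - mean(d$pixels[, , k])), 0.5)
  }
  expect_error(degrade_resolution(img, 0), "factor")
})

test_that("checkerboard mixing: every degraded pixel is the 4-pixel mean", {
  green <- c(0L, 255L, 0L); soil <- c(120L, 85L, 60L)
  px <- array(0L, dim = c(8, 8, 3))
  for (i in 1:8) for (j in 1:8) {
    px[i, j, ] <- if ((i + j) %% 2 == 0) green else soil
  }
  img <- rgb_image(px)
  d <- degrade_resolution(img, 2)
  expected <- as.integer(round((green + soil) / 2))
  for (k in 1:3) expect_true(all(d$pixels[, , k] == expected[k]))
  # mixed pixels reclassify: the pure-green half was GA = 0.5, the blended
  # mean (60,170,30) is still green-hued, so GA rises to 1
  expect_equal(green_area(img), 0.5)
  expect_equal(green_area(d), 1)
})

test_that("crop-then-index equals index-on-crop", {
  set.seed(43)
  mosaic <- rgb_image(random_rgb_image(12, 20))
  g <- plot_grid("sub", 2, 3, 8, 10)
  crop <- crop_plot_grid(mosaic, g)$sub
  direct <- summarize_rgb_plot(mosaic$pixels[3:10, 4:13, , drop = FALSE])
  expect_equal(summarize_rgb_plot(crop), direct)
})

test_that("index tables round-trip with NA as empty cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  # header-only for zero records
  write_index_table(data.frame(plot_id = character(0), x = numeric(0)), path)
  expect_equal(nrow(read_index_table(path)), 0)
  expect_equal(names(read_index_table(path)), c("plot_id", "x"))

  tab <- data.frame(plot_id = sprintf("p%02d", 1:52),
                    ndvi = signif(runif(52), 6), ga = signif(runif(52), 6))
  tab$ndvi[5] <- NA
  expect_message(write_index_table(tab, path), "1 undefined")
  back <- read_index_table(path)
  expect_equal(back, tab)
})

test_that("band stacks round-trip through per-band TIFFs and a manifest", {
  set.seed(44)
  st <- band_stack(list("670" = matrix(runif(12), 3, 4),
                        "840" = matrix(runif(12), 3, 4)), plot_id = "p7")
  dir <- withr::local_tempdir()
  manifest <- write_band_stack(st, dir)
  back <- read_band_stack(manifest, plot_id = "p7")
  expect_equal(back$bands[["670"]], st$bands[["670"]], tolerance = 1e-6)
  expect_equal(back$bands[["840"]], st$bands[["840"]], tolerance = 1e-6)
  expect_error(read_band_stack(file.path(dir, "missing.csv")), "no such file")
})
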