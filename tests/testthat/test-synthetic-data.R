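# Synthetic canopy scenes and trials: endmember spectra, cover control,
# determinism, planted statistical structure.

test_that("endmember spectra have the expected vegetation/soil shapes", {
  expect_gt(leaf_soil_reflectance(840, "leaf", 0), leaf_soil_reflectance(670, "leaf", 0))
  soil <- vapply(c(670, 840), leaf_soil_reflectance, numeric(1), material = "soil")
  expect_lt((soil[2] - soil[1]) / (soil[2] + soil[1]), 0.2) # soil NDVI near 0
  # chlorosis raises red and lowers NIR monotonically
  cl <- seq(0, 1, by = 0.25)
  r670 <- vapply(cl, function(c) leaf_soil_reflectance(670, "leaf", c), numeric(1))
  r840 <- vapply(cl, function(c) leaf_soil_reflectance(840, "leaf", c), numeric(1))
  expect_true(all(diff(r670) > 0))
  expect_true(all(diff(r840) < 0))
  ndvi_of <- function(c) spectral_index("ndvi", list(
    "670" = leaf_soil_reflectance(670, "leaf", c),
    "840" = leaf_soil_reflectance(840, "leaf", c)))
  expect_lt(ndvi_of(1), ndvi_of(0))
  expect_error(leaf_soil_reflectance(999, "leaf"), "unsupported wavelength")
})

test_that("scenes hit the target cover and keep RGB/stack aligned", {
  sc0 <- generate_canopy_scene(scene_params(green_fraction = 0, seed = 1))
  expect_equal(green_area(sc0$rgb), 0)

  sc <- generate_canopy_scene(scene_params(green_fraction = 0.25,
                                           image_size = c(128, 128), seed = 5))
  expect_lt(abs(green_area(sc$rgb) - 0.25), 0.01)
  expect_lt(abs(sc$truth$true_green_fraction - 0.25), 0.01)
  expect_equal(dim(sc$rgb$pixels)[1:2], dim(sc$stack$bands[[1]]))
  expect_equal(sc$truth$n_canopy + sc$truth$n_soil, sc$truth$n_pixels)
})

test_that("scene generation is deterministic in the seed", {
  p <- scene_params(green_fraction = 0.3, chlorosis = 0.4, seed = 77)
  a <- generate_canopy_scene(p)
  b <- generate_canopy_scene(p)
  expect_identical(a$rgb$pixels, b$rgb$pixels)
  expect_identical(a$stack$bands, b$stack$bands)
})

test_that("chlorosis lowers mean-band NDVI at equal cover", {
  healthy <- generate_canopy_scene(scene_params(green_fraction = 0.3,
                                                chlorosis = 0, seed = 12))
  sick <- generate_canopy_scene(scene_params(green_fraction = 0.3,
                                             chlorosis = 1, seed = 12))
  expect_gt(summarize_spectral_plot(healthy$stack)$ndvi,
            summarize_spectral_plot(sick$stack)$ndvi)
})

test_that("default trial has 52 plots and is seed-reproducible", {
  a <- generate_trial(trial_design(image_size = c(24, 32), seed = 8))
  b <- generate_trial(trial_design(image_size = c(24, 32), seed = 8))
  expect_equal(nrow(a$records), 52)
  expect_equal(a$records, b$records)
  expect_identical(a$scenes[[13]]$rgb$pixels, b$scenes[[13]]$rgb$pixels)
})

test_that("degenerate design collapses within-treatment yield variance", {
  d <- trial_design(genotype_sd = 0, residual_sd = 0, cover_yield_slope = 0,
                    seed = 2)
  tr <- generate_trial(d, render = FALSE)
  v <- tapply(tr$records$grain_yield, tr$records$treatment, stats::var)
  expect_equal(as.numeric(v), c(0, 0))
  expect_equal(sort(unique(tr$records$grain_yield)), c(5.64, 7.50))
})

test_that("treatment mean yields recover the configured 5.64 and 7.50", {
  d <- trial_design(n_genotypes = 1000L, seed = 3)
  tr <- generate_trial(d, render = FALSE)
  m <- tapply(tr$records$grain_yield, tr$records$treatment, mean)
  se <- tapply(tr$records$grain_yield, tr$records$treatment,
               function(y) stats::sd(y) / sqrt(length(y)))
  expect_lt(abs(m[["NPF"]] - 5.64), 3 * se[["NPF"]])
  expect_lt(abs(m[["OP"]] - 7.50), 3 * se[["OP"]])
})

test_that("cover-yield correlation tracks the closed-form planted value", {
  planted <- planted_cover_yield_correlation(trial_design())
  # table-level: many seeds, true cover vs yield
  rs <- vapply(1:200, function(s) {
    tr <- generate_trial(trial_design(seed = s), render = FALSE)
    stats::cor(tr$records$true_cover, tr$records$grain_yield)
  }, numeric(1))
  expect_true(all(abs(rs - planted) < 0.15))
  # image-level: computed GA carries the same linkage
  for (s in 1:3) {
    tr <- generate_trial(trial_design(seed = s, image_size = c(64, 96)))
    ga <- vapply(tr$scenes, function(sc) green_area(sc$rgb), numeric(1))
    expect_lt(abs(stats::cor(ga, tr$records$grain_yield) - planted), 0.15)
  }
})

test_that("ranking by true cover matches ranking by mean-band NDVI", {
  covers <- seq(0.1, 0.45, by = 0.05)
  ndvi <- vapply(seq_along(covers), function(i) {
    sc <- generate_canopy_scene(scene_params(green_fraction = covers[i],
                                             chlorosis = 0.2, seed = 100 + i))
    summarize_spectral_plot(sc$stack)$ndvi
  }, numeric(1))
  expect_equal(order(ndvi), seq_along(covers))
})
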