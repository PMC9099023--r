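test_that("ROI means are exact on constructed images", {
  img <- simulate_brain_image(background_level = 100, noise_sd = 0,
                              dim_px = c(100, 100))
  anyroi <- roi(x_um = 10, y_um = 10, width_um = 30, height_um = 20)
  expect_equal(roi_mean(img, anyroi), 100)
  # half-0 / half-200 image, ROI straddling both halves equally
  img2 <- img
  img2$pixels[, 1:50] <- 0
  img2$pixels[, 51:100] <- 200
  straddle <- roi(x_um = 40, y_um = 20, width_um = 20, height_um = 20)
  expect_equal(roi_mean(img2, straddle), 100)
  expect_error(roi_mean(img, roi(x_um = 90, y_um = 0, width_um = 20,
                                 height_um = 10)),
               "outside the image")
})

test_that("micrometre geometry converts with half-open pixel rounding", {
  img <- simulate_brain_image(background_level = 1, noise_sd = 0,
                              scale_um_per_px = 2, dim_px = c(50, 50))
  r <- roi(x_um = 3, y_um = 0, width_um = 4, height_um = 2)
  # x 3..7 um at 2 um/px -> columns 2..4; y 0..2 um -> row 1
  expect_equal(length(chronobug:::roi_pixels(img, r)), 3)
})

test_that("background correction subtracts and survives constant offsets", {
  img <- simulate_brain_image(cbind(60, 60), 50, cell_sigma_um = 6,
                              background_level = 100, noise_sd = 0,
                              dim_px = c(120, 120))
  sig <- roi(x_um = 30, y_um = 30, width_um = 60, height_um = 60)
  bg <- roi(x_um = 95, y_um = 95, width_um = 20, height_um = 20,
            role = "background")
  ci <- corrected_intensity(img, sig, bg)
  img_off <- img
  img_off$pixels <- img_off$pixels + 37.5
  ci_off <- corrected_intensity(img_off, sig, bg)
  expect_equal(ci$corrected, ci_off$corrected, tolerance = 1e-9)
  expect_error(corrected_intensity(img, sig, sig), "overlap")
})

test_that("simulated blob intensity is recovered within 1% at zero noise", {
  amp <- 50; sigma <- 8
  img <- simulate_brain_image(cbind(100, 80), amp, cell_sigma_um = sigma,
                              background_level = 100, noise_sd = 0,
                              scale_um_per_px = 1, dim_px = c(160, 200))
  sig <- roi(x_um = 60, y_um = 40, width_um = 80, height_um = 80)
  bg <- roi(x_um = 150, y_um = 130, width_um = 20, height_um = 20)
  ci <- corrected_intensity(img, sig, bg)
  analytic <- amp * 2 * pi * sigma^2 / (80 * 80)   # Gaussian integral / area
  expect_lt(abs(ci$corrected - analytic) / analytic, 0.01)
})

test_that("per-brain values average hemispheres and flag singletons", {
  l <- tibble::tibble(raw_mean = 140, background_mean = 100, corrected = 40,
                      negative_flag = FALSE, hemisphere = "left")
  r <- dplyr::mutate(l, corrected = 60, hemisphere = "right")
  b <- brain_intensity(l, r)
  expect_equal(b$intensity, 50)
  expect_false(b$single_hemisphere_flag)
  b1 <- brain_intensity(l, NULL)
  expect_equal(b1$intensity, 40)
  expect_true(b1$single_hemisphere_flag)
  expect_equal(brain_intensity(l, l)$intensity, 40)
  expect_error(brain_intensity(NULL, NULL), "At least one")
})

test_that("group contrasts on simulated cohorts recover the injected direction", {
  # two cohorts of brains differing in projection-field amplitude
  measure <- function(amp, seed) {
    img <- simulate_brain_image(cbind(60, 60), amp, cell_sigma_um = 10,
                                background_level = 100, noise_sd = 4,
                                dim_px = c(120, 120), seed = seed)
    sig <- roi(x_um = 20, y_um = 20, width_um = 70, height_um = 70)
    bg <- roi(x_um = 95, y_um = 95, width_um = 20, height_um = 20)
    corrected_intensity(img, sig, bg)$corrected
  }
  hits <- vapply(1:30, function(i) {
    mean(vapply(1:4, function(j) measure(45, i * 10 + j), numeric(1))) >
      mean(vapply(1:4, function(j) measure(30, i * 10 + j + 100), numeric(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
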