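# Width-averaged line profiles and half-depth envelope widths.

test_that("profiles of uniform and step images are exact", {
  img <- grey_image(matrix(7, 40, 40), pixel_size_nm = 1)
  p <- extract_profile(img, profile_line(c(5, 20), c(35, 20)))
  expect_true(all(p$grey == 7))
  expect_equal(p$distance_nm, 0:30)

  # vertical step (left 0, right 10), horizontal line: the perpendicular
  # offsets run parallel to the step, so averaging does not smear it
  step_px <- cbind(matrix(0, 40, 20), matrix(10, 40, 20))
  step_img <- grey_image(step_px, pixel_size_nm = 1)
  sp <- extract_profile(step_img, profile_line(c(3.5, 20), c(36.5, 20)))
  expect_true(all(sp$grey %in% c(0, 5, 10)))
  expect_equal(sum(sp$grey == 5), 1L)  # single transition sample
  expect_equal(rle(sp$grey)$values, c(0, 5, 10))
})

test_that("profile extraction commutes with affine grey rescaling, exactly", {
  band <- generate_band_image(band_image_model(80, seed = 5, angle_deg = 20))
  line <- band_profile_line(band)
  p0 <- extract_profile(band$image, line)
  img2 <- grey_image(3.5 * band$image$pixels - 40, band$image$pixel_size_nm)
  p1 <- extract_profile(img2, line)
  expect_equal(p1$grey, 3.5 * p0$grey - 40, tolerance = 1e-12)
  expect_equal(p1$distance_nm, p0$distance_nm)
})

test_that("a 45-degree rotated band yields the same profile as the unrotated band", {
  m0 <- band_image_model(60, size = c(300, 300), blur_sigma_nm = 4,
                         noise_sd = 0, angle_deg = 0)
  m45 <- band_image_model(60, size = c(300, 300), blur_sigma_nm = 4,
                          noise_sd = 0, angle_deg = 45)
  p0 <- extract_profile(generate_band_image(m0)$image,
                        band_profile_line(generate_band_image(m0),
                                          half_length_px = 60))
  p45 <- extract_profile(generate_band_image(m45)$image,
                         band_profile_line(generate_band_image(m45),
                                           half_length_px = 60))
  contrast <- abs(m0$band_grey - m0$background_grey)
  rms <- sqrt(mean((p0$grey - p45$grey)^2))
  expect_lt(rms / contrast, 0.02)
})

test_that("the averaging band must stay inside the image", {
  img <- grey_image(matrix(1, 30, 30), 1)
  expect_error(extract_profile(img, profile_line(c(2, 2), c(28, 2))),
               class = "sporesort_out_of_bounds")  # band of 23 exits the top
  expect_error(extract_profile(img, profile_line(c(-5, 15), c(28, 15))),
               class = "sporesort_out_of_bounds")
  expect_error(profile_line(c(1, 1), c(1, 1)), class = "sporesort_validation")
  expect_error(profile_line(c(1, 1), c(2, 2), averaging_width = 4),
               class = "sporesort_validation")
})

test_that("half-depth width is exact on rectangle and Gaussian dips", {
  d <- seq(0, 200, by = 1)

  rect <- data.frame(distance_nm = d,
                     grey = ifelse(d >= 81 & d <= 120, 0, 10))
  w_rect <- measure_envelope_width(rect, baseline_region = c(0, 60))
  expect_equal(as.numeric(w_rect), 40)

  sigma <- 17
  gauss <- data.frame(distance_nm = d,
                      grey = 10 - 10 * exp(-(d - 100)^2 / (2 * sigma^2)))
  w_gauss <- measure_envelope_width(gauss, baseline_region = c(0, 40))
  expect_equal(as.numeric(w_gauss), 2 * sqrt(2 * log(2)) * sigma,
               tolerance = 0.5 / 40)  # within half a sample of the FWHM

  # a bright band (rise) is measured the same way
  rise <- data.frame(distance_nm = d, grey = 10 - rect$grey)
  expect_equal(as.numeric(measure_envelope_width(rise, c(0, 60))), 40)
})

test_that("width measurement is affine-invariant in grey and linear in pixel size", {
  band <- generate_band_image(band_image_model(120, seed = 9))
  line <- band_profile_line(band)
  prof <- extract_profile(band$image, line)
  dmax <- max(prof$distance_nm)
  base <- list(c(0, 25), c(dmax - 25, dmax))
  w0 <- as.numeric(measure_envelope_width(prof, base))

  aff <- prof
  aff$grey <- -2 * prof$grey + 500
  expect_equal(as.numeric(measure_envelope_width(aff, base)), w0,
               tolerance = 1e-9)

  # halving the pixel size halves the measured physical width
  img_half <- grey_image(band$image$pixels, band$image$pixel_size_nm / 2)
  prof_half <- extract_profile(img_half, line)
  dm <- max(prof_half$distance_nm)
  w_half <- measure_envelope_width(prof_half,
                                   list(c(0, 12.5), c(dm - 12.5, dm)))
  expect_equal(as.numeric(w_half), w0 / 2, tolerance = 1e-9)
})

test_that("degenerate profiles raise the documented conditions", {
  d <- seq(0, 100, by = 1)
  flat <- data.frame(distance_nm = d, grey = rep(4, length(d)))
  expect_error(measure_envelope_width(flat, c(0, 20)),
               class = "sporesort_feature_not_found")

  two_dips <- data.frame(distance_nm = d,
                         grey = 10 - 10 * (d >= 20 & d <= 30) -
                           9.5 * (d >= 60 & d <= 70))
  expect_error(measure_envelope_width(two_dips, c(40, 55)),
               class = "sporesort_ambiguous_feature")

  edge <- data.frame(distance_nm = d, grey = ifelse(d <= 30, 0, 10))
  expect_error(measure_envelope_width(edge, c(60, 100)),
               class = "sporesort_feature_not_found")
})

test_that("width summaries are hierarchical means with display-only rounding", {
  one <- summarize_widths(list(cellA = 42.42))
  expect_equal(one$overall_mean, 42.42)

  set <- summarize_widths(list(c1 = c(60, 66), c2 = c(40, 44)))
  expect_equal(unname(set$cell_means), c(63, 42))
  expect_equal(set$overall_mean, 52.5)

  df <- data.frame(cell = rep(c("a", "b"), each = 2),
                   width_nm = c(1, 3, 5, 7))
  expect_equal(summarize_widths(df)$overall_mean, 4)

  expect_error(summarize_widths(list()), class = "sporesort_empty_input")
  expect_error(summarize_widths(list(a = numeric())),
               class = "sporesort_empty_input")
})

test_that("grey images round-trip through TIFF within quantization error", {
  band <- generate_band_image(band_image_model(60, seed = 2))
  path <- withr::local_tempfile(fileext = ".tif")
  write_grey_image(band$image, path)
  back <- read_grey_image(path, band$image$pixel_size_nm)
  expect_equal(dim(back$pixels), dim(band$image$pixels))
  # stored on a 0-255/16-bit scale: compare after rescaling
  expect_equal(back$pixels * 255, band$image$pixels, tolerance = 0.01)
})
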