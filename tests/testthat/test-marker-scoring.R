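# Marker catalog, peak detection and signature scoring.

test_that("the default catalog carries the documented band set", {
  cat_df <- as.data.frame(default_catalog())
  cadpa <- cat_df$center[cat_df$assignment == "CaDPA" |
                           grepl("^CaDPA", cat_df$assignment)]
  expect_setequal(cadpa, c(1017, 1395, 1446))
  expect_setequal(cat_df$center[cat_df$phenotypes == "cyst"],
                  c(830, 1150, 1350))
  expect_setequal(cat_df$center[cat_df$phenotypes == "exospore"],
                  c(1342, 1586))
  expect_setequal(cat_df$center[cat_df$phenotypes == "myxospore"],
                  c(1120, 1149, 1550))
  expect_true(1505 %in% cat_df$center)  # alias reading of the 1550 band
  expect_true(2295 %in% cat_df$center)
  expect_true(2900 %in% cat_df$center)
  expect_true(all(nzchar(cat_df$phenotypes)))
})

test_that("catalogs round-trip through their CSV serialization", {
  cat0 <- default_catalog()
  path <- withr::local_tempfile(fileext = ".csv")
  write_catalog(cat0, path)
  back <- read_catalog(path)
  expect_equal(as.data.frame(back), as.data.frame(cat0))
  expect_error(marker_catalog(list(marker_peak(1000, 10, "x", "a"),
                                   marker_peak(1000, 12, "y", "a"))),
               class = "sporesort_validation")
  expect_error(marker_peak(1000, 10, "x", character()),
               class = "sporesort_validation")
})

test_that("detect_peaks recovers isolated Gaussians to within the spectral resolution", {
  # single peak
  one <- generate_spectrum(spectrum_model(list(peak_spec(1395, 2)),
                                          baseline = 0.1, noise_sd = 0))
  det <- detect_peaks(one)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$position - 1395), 3.5)

  # k well-separated Gaussians, k = 2..5
  centers_pool <- c(900, 1200, 1500, 2100, 2700)
  for (k in 2:5) {
    centers <- centers_pool[seq_len(k)]
    model <- spectrum_model(lapply(centers, function(c0) peak_spec(c0, 2)),
                            baseline = 0.1, noise_sd = 0)
    det_k <- detect_peaks(generate_spectrum(model))
    expect_equal(nrow(det_k), k)
    expect_true(all(abs(det_k$position - centers) < 3.5))
  }

  expect_equal(nrow(detect_peaks(flat_spectrum(1))), 0L)
})

test_that("detection agrees with an independent peak finder on a noiseless preset", {
  s <- preset_spectrum("endospore")
  det <- detect_peaks(s)
  ref <- pracma::findpeaks(s$intensity,
                           minpeakheight = min(s$intensity) +
                             0.05 * diff(range(s$intensity)))
  ref_pos <- sort(s$wavenumber[ref[, 2]])
  expect_setequal(round(det$position, 6), round(ref_pos, 6))
})

test_that("close doublets are thinned to the taller peak", {
  wn <- seq(1000, 1100, by = 1)
  y <- 0.1 + 2 * exp(-4 * log(2) * (wn - 1050)^2 / 9) +
    1.5 * exp(-4 * log(2) * (wn - 1052)^2 / 9)
  s <- raman_spectrum(wn, y)
  det <- detect_peaks(s, min_separation = 10)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$position - 1050.5), 2)
  expect_equal(det$height, max(y))
})

test_that("detected prominences never exceed height minus the global minimum", {
  for (seed in 1:10) {
    s <- random_spectrum(seed, n = 200, lo = 800, hi = 1800)
    det <- detect_peaks(s, min_prominence = 0.01)
    if (nrow(det) > 0)
      expect_true(all(det$prominence <= det$height - min(s$intensity) + 1e-12))
  }
})

test_that("signature scores are scale-invariant and monotone under added peaks", {
  s <- preset_spectrum("endospore")
  for (a in c(0.2, 1, 40)) {
    sc <- s
    sc$intensity <- a * s$intensity
    expect_equal(signature_score(sc, "endospore"),
                 signature_score(s, "endospore"))
  }

  # adding an unrelated peak never decreases any phenotype's score
  base_model <- phenotype_preset("cyst", noise_sd = 0)
  plus_model <- spectrum_model(
    peaks = c(base_model$peaks, list(peak_spec(2500, 1.5))),
    baseline = base_model$baseline[1], noise_sd = 0)
  s0 <- generate_spectrum(base_model)
  s1 <- generate_spectrum(plus_model)
  for (ph in c("endospore", "exospore", "myxospore", "cyst",
               "akinete_vegetative", "vegetative"))
    expect_gte(signature_score(s1, ph), signature_score(s0, ph))
})

test_that("noiseless presets score 1 on their own signature, 0 against disjoint ones", {
  expect_equal(signature_score(preset_spectrum("endospore"), "endospore"), 1)
  expect_equal(signature_score(preset_spectrum("cyst"), "endospore"), 0)
  expect_equal(signature_score(preset_spectrum("cyst"), "cyst"), 1)
  for (ph in c("endospore", "exospore", "myxospore", "cyst",
               "akinete_vegetative", "vegetative"))
    expect_equal(signature_score(flat_spectrum(1), ph), 0)
  expect_error(signature_score(flat_spectrum(1), "not_a_phenotype"),
               class = "sporesort_catalog_miss")
})

test_that("marker recovery survives the default noise level", {
  for (seed in 1:10) {
    s <- preset_spectrum("endospore", noise_sd = 0.12, seed = seed)
    expect_equal(signature_score(s, "endospore"), 1)
  }
})
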