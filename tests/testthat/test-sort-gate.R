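# The Pc / P_CaDPA statistics and the two-threshold decision.

test_that("Pc is 1 for cell == medium and a rectangle ratio for flat spectra", {
  med <- preset_spectrum("medium")
  expect_equal(compute_pc(med, med), 1.0)
  expect_equal(compute_pc(flat_spectrum(3), flat_spectrum(2)), 1.5)
})

test_that("Pc is homogeneous in the cell spectrum", {
  med <- preset_spectrum("medium")
  for (seed in 1:10) {
    s <- random_spectrum(seed, n = 120, lo = 1600, hi = 1700)
    pc <- compute_pc(s, med)
    for (a in c(0.3, 2.5)) {
      sa <- s
      sa$intensity <- a * s$intensity
      expect_equal(compute_pc(sa, med), a * pc, tolerance = 1e-12)
    }
  }
})

test_that("Pc resamples the medium when the axes differ", {
  cell <- flat_spectrum(3, lo = 1600, hi = 1700, step = 2)
  med <- flat_spectrum(2, lo = 1500, hi = 1800, step = 3.7)
  expect_equal(compute_pc(cell, med), 1.5, tolerance = 1e-12)
  # medium not covering the window
  short_med <- flat_spectrum(2, lo = 1640, hi = 1700, step = 1)
  expect_error(compute_pc(cell, short_med), class = "sporesort_out_of_span")
  zero_med <- flat_spectrum(0, lo = 1500, hi = 1800)
  expect_error(compute_pc(cell, zero_med),
               class = "sporesort_invalid_reference")
})

test_that("P_CaDPA is 1 on flat spectra in both modes and scale-invariant", {
  f <- flat_spectrum(2)
  expect_equal(compute_pcadpa(f, mode = "max"), 1.0)
  expect_equal(compute_pcadpa(f, mode = "integrated"), 1.0)

  # window maxima 5 (CaDPA region) vs 4 (cell region)
  wn <- seq(1300, 1750, by = 5)
  y <- rep(4, length(wn))
  y[wn == 1395] <- 5
  expect_equal(compute_pcadpa(raman_spectrum(wn, y), mode = "max"), 1.25)

  for (seed in 1:10) {
    r <- random_spectrum(seed, n = 200, lo = 1300, hi = 1750)
    for (mode in c("max", "integrated")) {
      p0 <- compute_pcadpa(r, mode = mode)
      for (a in c(0.3, 7)) {
        ra <- r
        ra$intensity <- a * r$intensity
        expect_equal(compute_pcadpa(ra, mode = mode), p0, tolerance = 1e-12)
      }
    }
  }
})

test_that("a non-negative bump inside the CaDPA window never lowers P_CaDPA", {
  base <- phenotype_preset("vegetative_firmicute", noise_sd = 0)
  s0 <- generate_spectrum(base)
  for (amp in c(0.1, 0.5, 2, 8)) {
    bumped <- spectrum_model(
      peaks = c(base$peaks, list(peak_spec(1395, amp, fwhm = 10))),
      baseline = base$baseline[1], noise_sd = 0)
    s1 <- generate_spectrum(bumped)
    for (mode in c("max", "integrated"))
      expect_gte(compute_pcadpa(s1, mode = mode),
                 compute_pcadpa(s0, mode = mode))
  }
})

test_that("classification follows the two-stage gate with >= boundary rule", {
  med <- preset_spectrum("medium")

  # cell identical to the medium: Pc = 1 passes stage 1 (boundary rule),
  # flat-ish ratio stays below the endospore threshold
  r_same <- classify_spectrum(med, med)
  expect_equal(r_same$pc, 1.0)
  expect_equal(r_same$decision, "vegetative")

  # flat cell at twice the medium
  r_flat <- classify_spectrum(flat_spectrum(2), flat_spectrum(1))
  expect_equal(r_flat$pc, 2.0)
  expect_equal(r_flat$pcadpa, 1.0)
  expect_equal(r_flat$decision, "vegetative")

  r_spo <- classify_spectrum(preset_spectrum("endospore"), med)
  expect_equal(r_spo$decision, "endospore")
  expect_gte(r_spo$pcadpa, 1.1)

  r_deb <- classify_spectrum(preset_spectrum("debris"), med)
  expect_equal(r_deb$decision, "waste")
  expect_true(is.na(r_deb$pcadpa))  # stage 2 never reached
})

test_that("batch classification preserves order, records errors, counts sum", {
  med <- preset_spectrum("medium")

  ten <- raman_collection(lapply(1:10, function(i) {
    s <- med
    s$meta$label <- sprintf("m%02d", i)
    s
  }))
  b <- batch_classify(ten, med)
  expect_equal(unname(b$counts[c("waste", "vegetative")]), c(0L, 10L))
  expect_equal(b$results$label, sprintf("m%02d", 1:10))

  empty <- batch_classify(raman_collection(list()), med)
  expect_equal(nrow(empty$results), 0L)
  expect_equal(sum(empty$counts), 0L)

  # a spectrum not covering the gate windows is recorded, not fatal
  broken <- raman_spectrum(seq(2000, 3000, 10), rep(1, 101), label = "bad")
  mix <- raman_collection(list(preset_spectrum("endospore"), broken,
                               preset_spectrum("debris")))
  bm <- batch_classify(mix, med)
  expect_equal(bm$results$decision, c("endospore", "error", "waste"))
  expect_match(bm$results$note[2], "window")
  expect_equal(sum(bm$counts), length(mix))
})

test_that("exactly one decision per non-error spectrum on a mixed population", {
  med <- preset_spectrum("medium")
  pop <- generate_population(c(endospore = 5, vegetative_firmicute = 5,
                               cyst = 5, debris = 5), seed = 3)
  b <- batch_classify(pop, med)
  expect_equal(b$counts[["error"]], 0L)
  expect_true(all(b$results$decision %in%
                    c("waste", "vegetative", "endospore")))
  expect_equal(sum(b$counts), 20L)
})

test_that("window and threshold containers validate their invariants", {
  expect_error(gate_windows(spectral_window(1620, 1670),
                            spectral_window(1600, 1700)),
               class = "sporesort_validation")
  expect_error(gate_thresholds(pc_threshold = -1),
               class = "sporesort_validation")
  expect_error(spectral_window(1700, 1600), class = "sporesort_validation")
})
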