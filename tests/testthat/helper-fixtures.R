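# Shared fixtures: all built in code, nothing read from disk.

# A constant-intensity spectrum on a regular axis.
flat_spectrum <- function(value = 1, lo = 800, hi = 3300, step = 3.5, ...) {
  wn <- seq(lo, hi, by = step)
  raman_spectrum(wn, rep(value, length(wn)), ...)
}

# A strictly positive random spectrum on a regular axis (seeded).
random_spectrum <- function(seed, n = 60, lo = 1300, hi = 1700) {
  set.seed(seed)
  wn <- seq(lo, hi, length.out = n)
  raman_spectrum(wn, stats::runif(n, 0.1, 5))
}

# Noiseless preset spectrum, the workhorse of gate/scoring tests.
preset_spectrum <- function(tag, noise_sd = 0, seed = 1L) {
  generate_spectrum(phenotype_preset(tag, noise_sd = noise_sd), seed = seed)
}

# Independent integration oracle: midpoint rule on a 10x-supersampled
# piecewise-linear interpolant over the (axis-clipped) window breadth. Exact
# for piecewise-linear functions, so it must agree with the trapezoid rule
# without sharing its code path.
midpoint_integral <- function(spectrum, window) {
  a <- max(window$lo, min(spectrum$wavenumber))
  b <- min(window$hi, max(spectrum$wavenumber))
  inner <- spectrum$wavenumber[spectrum$wavenumber > a &
                                 spectrum$wavenumber < b]
  knots <- unique(c(a, inner, b))
  # subdivide every knot interval into 10 so each fine midpoint lies inside
  # one linear piece (the midpoint rule is exact there)
  fine <- unique(unlist(lapply(seq_len(length(knots) - 1L), function(i)
    seq(knots[i], knots[i + 1L], length.out = 11L))))
  mids <- (fine[-1L] + fine[-length(fine)]) / 2
  vals <- stats::approx(spectrum$wavenumber, spectrum$intensity,
                        xout = mids)$y
  sum(vals * diff(fine))
}

expect_spectra_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$wavenumber, b$wavenumber, tolerance = tol)
  expect_equal(a$intensity, b$intensity, tolerance = tol)
}
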