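# Primitive spectral operations: min-max normalization, window cropping,
# window statistics (trapezoidal integral, in-window maximum) and linear
# resampling. No smoothing, despiking or baseline subtraction is performed
# anywhere in the package: spectra are used raw, and normalization is a
# display/export convenience only (the sorting ratios are computed on raw
# intensities so that the cell/medium comparison stays commensurate).

#' A closed spectral window
#'
#' @param lo,hi Window bounds in cm^-1, `0 < lo < hi < 4000`. Both bounds are
#'   inclusive throughout the package: a sample exactly at `lo` or `hi`
#'   belongs to the window.
#' @return Object of class `spectral_window`.
#' @examples
#' cell_region <- spectral_window(1620, 1670)
#' @export
spectral_window <- function(lo, hi) {
  stopifnot_scalar_number(lo, "lo")
  stopifnot_scalar_number(hi, "hi")
  if (lo >= hi)
    ss_abort(sprintf("window lo (%g) must be < hi (%g)", lo, hi),
             "sporesort_validation")
  if (lo <= 0 || hi >= 4000)
    ss_abort("window bounds must lie inside the Raman-shift range (0, 4000)",
             "sporesort_validation")
  structure(list(lo = as.double(lo), hi = as.double(hi)),
            class = "spectral_window")
}

#' @export
print.spectral_window <- function(x, ...) {
  cat(sprintf("<spectral_window> [%g, %g] cm^-1\n", x$lo, x$hi))
  invisible(x)
}

assert_window <- function(w) {
  if (!inherits(w, "spectral_window"))
    ss_abort("expected a spectral_window", "sporesort_validation")
  invisible(w)
}

window_index <- function(spectrum, window) {
  which(spectrum$wavenumber >= window$lo & spectrum$wavenumber <= window$hi)
}

#' Min-max normalize a spectrum
#'
#' Rescales intensities to `(I - I_min) / (I_max - I_min)`, so the output
#' spans exactly \[0, 1\]. The wavenumber axis is untouched and the metadata
#' gains a `normalized` flag. Idempotent: normalizing twice equals
#' normalizing once.
#'
#' @param spectrum A [raman_spectrum].
#' @return The normalized [raman_spectrum].
#' @export
minmax_normalize <- function(spectrum) {
  assert_spectrum(spectrum)
  lo <- min(spectrum$intensity)
  hi <- max(spectrum$intensity)
  if (hi == lo)
    ss_abort("constant spectrum: min-max normalization would divide by zero",
             "sporesort_degenerate_spectrum")
  spectrum$intensity <- (spectrum$intensity - lo) / (hi - lo)
  spectrum$meta$normalized <- TRUE
  spectrum$meta$has_negative <- FALSE
  spectrum
}

#' Crop a spectrum to a window
#'
#' Keeps the samples with `lo <= wavenumber <= hi` (boundary samples
#' included).
#'
#' @param spectrum A [raman_spectrum].
#' @param window A [spectral_window].
#' @return The sub-spectrum.
#' @export
crop_window <- function(spectrum, window) {
  assert_spectrum(spectrum)
  assert_window(window)
  idx <- window_index(spectrum, window)
  if (length(idx) == 0L)
    ss_abort(sprintf("window [%g, %g] contains no samples of the spectrum",
                     window$lo, window$hi), "sporesort_empty_window")
  spectrum$wavenumber <- spectrum$wavenumber[idx]
  spectrum$intensity <- spectrum$intensity[idx]
  spectrum
}

# Integration knots for a window: the in-window samples plus linearly
# interpolated values at the (axis-clipped) window edges, so the integral
# covers the window's full breadth and a flat spectrum integrates to
# value * breadth regardless of how the sampling grid falls.
window_knots <- function(spectrum, window) {
  a <- max(window$lo, min(spectrum$wavenumber))
  b <- min(window$hi, max(spectrum$wavenumber))
  idx <- window_index(spectrum, window)
  x <- unique(c(a, spectrum$wavenumber[idx], b))
  list(x = x,
       y = stats::approx(spectrum$wavenumber, spectrum$intensity, xout = x,
                         method = "linear", ties = "ordered")$y,
       n_samples = length(idx))
}

#' Trapezoidal integrated intensity over a window
#'
#' Integrates intensity over wavenumber with the trapezoid rule on the native
#' (possibly non-uniform) axis. The integration knots are the in-window
#' samples plus linearly interpolated values at the window edges, so the
#' integral spans the window's exact breadth (clipped to the axis span). This
#' is the "integrated intensity" entering the sorting ratios.
#'
#' @inheritParams crop_window
#' @return Scalar integral in a.u. * cm^-1.
#' @export
integrate_window <- function(spectrum, window) {
  assert_spectrum(spectrum)
  assert_window(window)
  k <- window_knots(spectrum, window)
  if (k$n_samples < 2L)
    ss_abort(sprintf(
      "window [%g, %g] holds %d sample(s); >= 2 needed for integration",
      window$lo, window$hi, k$n_samples), "sporesort_insufficient_samples")
  pracma::trapz(k$x, k$y)
}

#' Maximum intensity within a window
#'
#' The maximum over in-window samples; no interpolation beyond samples.
#'
#' @inheritParams crop_window
#' @return Scalar maximum intensity (a.u.).
#' @export
max_in_window <- function(spectrum, window) {
  assert_spectrum(spectrum)
  assert_window(window)
  idx <- window_index(spectrum, window)
  if (length(idx) == 0L)
    ss_abort(sprintf("window [%g, %g] contains no samples",
                     window$lo, window$hi), "sporesort_empty_window")
  max(spectrum$intensity[idx])
}

#' Resample a spectrum onto a target wavenumber axis
#'
#' Linear interpolation of intensities onto `axis`. Extrapolation is refused:
#' every target wavenumber must lie within the source span.
#'
#' @param spectrum A [raman_spectrum].
#' @param axis Numeric vector of target wavenumbers (cm^-1).
#' @return A [raman_spectrum] on the target axis, metadata carried over.
#' @export
resample_to_axis <- function(spectrum, axis) {
  assert_spectrum(spectrum)
  if (!is.numeric(axis) || length(axis) < 1L)
    ss_abort("target axis must be a non-empty numeric vector",
             "sporesort_validation")
  src_lo <- min(spectrum$wavenumber)
  src_hi <- max(spectrum$wavenumber)
  if (min(axis) < src_lo || max(axis) > src_hi)
    ss_abort(sprintf(
      "target axis [%g, %g] exceeds source span [%g, %g]: extrapolation refused",
      min(axis), max(axis), src_lo, src_hi), "sporesort_out_of_span")
  y <- stats::approx(spectrum$wavenumber, spectrum$intensity, xout = axis,
                     method = "linear", ties = "ordered")$y
  out <- spectrum
  out$wavenumber <- as.double(axis[order(axis)])
  out$intensity <- y[order(axis)]
  out$meta$has_negative <- any(out$intensity < 0)
  out
}
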