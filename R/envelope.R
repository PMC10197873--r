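# Cell-envelope morphometry on electron micrographs.
#
# A width-averaged line profile is drawn perpendicular to the envelope (the
# micrograph analysis convention: a profile line of width 23 pixels, i.e. 23
# parallel 1-pixel profiles averaged, to reduce noise), and the envelope
# width is read off the profile as the distance between the two half-depth
# crossings of the envelope's dip (or rise) relative to a user-designated
# baseline region. Half-depth is affine-invariant in grey value and reduces
# to the intuitive edge-to-edge distance for step-like envelopes.

#' Construct a grey-scale image
#'
#' @param pixels Numeric matrix of grey values; rows index y, columns x.
#'   Pixel centers sit at integer coordinates: pixel `(x = j, y = i)` is
#'   `pixels[i, j]`.
#' @param pixel_size_nm Physical pixel size in nm per pixel (> 0).
#' @return Object of class `grey_image`.
#' @export
grey_image <- function(pixels, pixel_size_nm) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L)
    ss_abort("pixels must be a non-empty numeric matrix", "sporesort_validation")
  if (any(!is.finite(pixels)))
    ss_abort("grey values must be finite", "sporesort_validation")
  stopifnot_scalar_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  structure(list(pixels = pixels, pixel_size_nm = as.double(pixel_size_nm)),
            class = "grey_image")
}

#' @export
print.grey_image <- function(x, ...) {
  cat(sprintf("<grey_image> %d x %d px at %g nm/px (grey %g..%g)\n",
              ncol(x$pixels), nrow(x$pixels), x$pixel_size_nm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a grey-scale TIFF or PNG image
#'
#' Multi-channel images are averaged to one grey channel. Grey values are
#' kept on whatever scale the reader returns (all downstream measurements are
#' affine-invariant in grey value).
#'
#' @param path Image file (`.tif`/`.tiff` or `.png`).
#' @param pixel_size_nm Physical pixel size in nm per pixel.
#' @return A [grey_image].
#' @export
read_grey_image <- function(path, pixel_size_nm) {
  if (!file.exists(path))
    ss_abort(sprintf("file '%s' does not exist", path), "sporesort_io")
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                ss_abort(sprintf("unsupported image format '.%s'", ext),
                         "sporesort_io"))
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1L, 2L), mean)
  grey_image(arr, pixel_size_nm)
}

#' Write a grey image as TIFF
#'
#' Grey values are clamped to \[0, 255\] and stored as 16-bit intensities on
#' a 0-255 scale.
#'
#' @param image A [grey_image].
#' @param path Output `.tif` path.
#' @return The path, invisibly.
#' @export
write_grey_image <- function(image, path) {
  px <- pmin(pmax(image$pixels, 0), 255) / 255
  tiff::writeTIFF(px, path, bits.per.sample = 16L)
  invisible(path)
}

#' A width-averaged profile line
#'
#' @param start,end Continuous pixel coordinates `c(x, y)`; must differ.
#' @param averaging_width Number of 1-pixel-spaced parallel profiles averaged
#'   along the unit perpendicular; odd, >= 1. Default 23, the noise-reduction
#'   convention the envelope measurements follow.
#' @return Object of class `profile_line`.
#' @export
profile_line <- function(start, end, averaging_width = 23) {
  if (!is.numeric(start) || length(start) != 2L ||
      !is.numeric(end) || length(end) != 2L)
    ss_abort("start and end must be numeric c(x, y)", "sporesort_validation")
  if (all(start == end))
    ss_abort("start and end must differ", "sporesort_validation")
  w <- as.integer(averaging_width)
  if (w < 1L || w %% 2L == 0L)
    ss_abort("averaging_width must be odd and >= 1", "sporesort_validation")
  structure(list(start = as.double(start), end = as.double(end),
                 averaging_width = w),
            class = "profile_line")
}

# Vectorized bilinear interpolation at continuous coordinates (x, y).
bilinear <- function(pixels, x, y) {
  nr <- nrow(pixels)
  nc <- ncol(pixels)
  x0 <- pmin(floor(x), nc - 1L)
  y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0
  fy <- y - y0
  idx <- function(yy, xx) pixels[cbind(yy, xx)]
  idx(y0, x0) * (1 - fx) * (1 - fy) + idx(y0, x0 + 1L) * fx * (1 - fy) +
    idx(y0 + 1L, x0) * (1 - fx) * fy + idx(y0 + 1L, x0 + 1L) * fx * fy
}

#' Extract a width-averaged density profile
#'
#' Samples the image at 1-pixel spacing along the line; each sample is the
#' mean of `averaging_width` bilinear interpolations taken at integer pixel
#' offsets `-(w-1)/2 ... +(w-1)/2` along the unit perpendicular. Distances
#' are converted to nm via the image's pixel size. The whole sampling band
#' must lie inside the image; out-of-grid samples are an error, not padded.
#'
#' Exactly affine-covariant in grey value: profiling `a * image + b` yields
#' `a * profile + b`.
#'
#' @param image A [grey_image].
#' @param line A [profile_line].
#' @return Object of class `density_profile`: a data.frame with columns
#'   `distance_nm` (from the line start, strictly increasing from 0) and
#'   `grey` (mean grey value).
#' @export
extract_profile <- function(image, line) {
  if (!inherits(image, "grey_image"))
    ss_abort("expected a grey_image", "sporesort_validation")
  if (!inherits(line, "profile_line"))
    ss_abort("expected a profile_line", "sporesort_validation")
  px <- image$pixels
  d <- line$end - line$start
  len <- sqrt(sum(d^2))
  u <- d / len
  perp <- c(-u[2L], u[1L])
  t <- seq(0, floor(len))
  offsets <- seq(-(line$averaging_width - 1L) / 2,
                 (line$averaging_width - 1L) / 2)
  xs <- outer(line$start[1L] + t * u[1L], offsets * perp[1L], `+`)
  ys <- outer(line$start[2L] + t * u[2L], offsets * perp[2L], `+`)
  if (min(xs) < 1 || max(xs) > ncol(px) || min(ys) < 1 || max(ys) > nrow(px))
    ss_abort("profile line (including its averaging band) exits the image",
             "sporesort_out_of_bounds")
  vals <- matrix(bilinear(px, as.vector(xs), as.vector(ys)), nrow = length(t))
  structure(data.frame(distance_nm = t * image$pixel_size_nm,
                       grey = rowMeans(vals)),
            class = c("density_profile", "data.frame"),
            pixel_size_nm = image$pixel_size_nm)
}

in_intervals <- function(x, intervals) {
  if (is.numeric(intervals) && length(intervals) == 2L)
    intervals <- list(intervals)
  hit <- rep(FALSE, length(x))
  for (iv in intervals) {
    if (!is.numeric(iv) || length(iv) != 2L)
      ss_abort("baseline_region must be c(lo, hi) or a list of such intervals",
               "sporesort_validation")
    hit <- hit | (x >= min(iv) & x <= max(iv))
  }
  hit
}

#' Measure an envelope width from a density profile
#'
#' Half-depth criterion: the baseline grey is the mean over
#' `baseline_region`; the feature is the profile's largest excursion from the
#' baseline (dip for a dark envelope on a brighter background, or rise); the
#' width is the distance between the two crossings of the level halfway
#' between baseline and feature extreme, located by linear interpolation
#' between samples. Affine-invariant in grey value; scales linearly with the
#' pixel size.
#'
#' @param profile A [density_profile] from [extract_profile()] (or any
#'   data.frame with `distance_nm` and `grey` columns).
#' @param baseline_region Distance interval `c(lo, hi)` in nm lying outside
#'   the feature, or a list of such intervals (e.g. one on each side).
#' @param method Width criterion; only `"half_depth"` is implemented.
#' @return Width in nm, with attributes `baseline`, `level`, `crossings_nm`
#'   and `extreme_nm`.
#' @export
measure_envelope_width <- function(profile, baseline_region,
                                   method = "half_depth") {
  method <- match.arg(method, "half_depth")
  d <- profile$distance_nm
  v <- profile$grey
  if (is.null(d) || is.null(v) || length(d) < 3L)
    ss_abort("profile must have distance_nm and grey columns (>= 3 samples)",
             "sporesort_validation")
  base_idx <- which(in_intervals(d, baseline_region))
  if (length(base_idx) == 0L)
    ss_abort("baseline_region contains no profile samples",
             "sporesort_validation")
  baseline <- mean(v[base_idx])
  dev <- v - baseline
  i_ext <- which.max(abs(dev))
  depth <- dev[i_ext]
  if (depth == 0)
    ss_abort("profile is flat relative to the baseline: no feature",
             "sporesort_feature_not_found")
  sgn <- sign(depth)
  half <- abs(depth) / 2
  beyond <- sgn * dev > half
  runs <- rle(beyond)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  feat_runs <- which(runs$values)
  # Candidate features: half-level runs reaching at least 80% of the main
  # excursion. More than one such run means the profile crosses several
  # comparable features and the measurement would be ambiguous.
  run_depth <- vapply(feat_runs, function(r)
    max(sgn * dev[starts[r]:ends[r]]), numeric(1L))
  cand <- feat_runs[run_depth >= 0.8 * abs(depth)]
  if (length(cand) > 1L)
    ss_abort(sprintf(
      "ambiguous profile: %d comparable features near %s nm",
      length(cand),
      paste(sprintf("%.1f", d[starts[cand]]), collapse = ", ")),
      "sporesort_ambiguous_feature")
  main <- feat_runs[starts[feat_runs] <= i_ext & ends[feat_runs] >= i_ext]
  a <- starts[main]
  b <- ends[main]
  if (a <= 1L || b >= length(v))
    ss_abort("feature touches the profile end: no half-depth crossing pair",
             "sporesort_feature_not_found")
  cross <- function(i0, i1) {
    # linear interpolation of the half-level crossing between samples i0, i1
    f <- (half - sgn * dev[i0]) / (sgn * dev[i1] - sgn * dev[i0])
    d[i0] + f * (d[i1] - d[i0])
  }
  left <- cross(a - 1L, a)
  right <- cross(b + 1L, b)
  width <- abs(right - left)
  attr(width, "baseline") <- baseline
  attr(width, "level") <- baseline + sgn * half
  attr(width, "crossings_nm") <- c(left, right)
  attr(width, "extreme_nm") <- d[i_ext]
  width
}

#' Summarize repeated per-cell envelope-width measurements
#'
#' Computes the arithmetic mean of each cell's repeated measurements and the
#' overall mean of the cell means (the hierarchical average reported for
#' five measurements per image over five cells). Values are kept unrounded
#' internally; the print method displays 2 decimals.
#'
#' @param measurements Named list of numeric vectors (one entry per cell,
#'   each holding that cell's repeated width measurements in nm), or a
#'   data.frame with columns `cell` and `width_nm`.
#' @return Object of class `envelope_width_set`: list with `per_cell`,
#'   `cell_means` and `overall_mean` (nm).
#' @examples
#' summarize_widths(list(c1 = 63.2, c2 = 41.6, c3 = 29.4, c4 = 39.8,
#'                       c5 = 49.6))$overall_mean  # 44.72
#' @export
summarize_widths <- function(measurements) {
  if (is.data.frame(measurements)) {
    if (!all(c("cell", "width_nm") %in% names(measurements)))
      ss_abort("data.frame input needs 'cell' and 'width_nm' columns",
               "sporesort_validation")
    measurements <- split(measurements$width_nm, measurements$cell)
  }
  if (!is.list(measurements) || length(measurements) == 0L)
    ss_abort("need at least one cell", "sporesort_empty_input")
  for (m in measurements)
    if (!is.numeric(m) || length(m) == 0L || anyNA(m))
      ss_abort("each cell needs at least one finite width measurement",
               "sporesort_empty_input")
  cell_means <- vapply(measurements, mean, numeric(1L))
  structure(list(per_cell = measurements, cell_means = cell_means,
                 overall_mean = mean(cell_means)),
            class = "envelope_width_set")
}

#' @export
print.envelope_width_set <- function(x, ...) {
  cat(sprintf("<envelope_width_set> %d cells\n", length(x$per_cell)))
  for (nm in names(x$cell_means))
    cat(sprintf("  %s: mean %.2f nm (%d measurement(s))\n", nm,
                x$cell_means[[nm]], length(x$per_cell[[nm]])))
  cat(sprintf("  overall mean: %.2f nm\n", x$overall_mean))
  invisible(x)
}

#' Reference per-cell envelope width measurements
#'
#' The packaged per-cell envelope width table (nm) for the four imaged
#' species in vegetative (VEG) and spore (SPO) form: five values per row
#' (one per cell; each is itself the average of five measurements on that
#' cell's image, except the akinete row, where all five measurements come
#' from a single cell).
#'
#' @return data.frame with columns `species`, `cell_type`, `cell_1` ...
#'   `cell_5` and `average_nm` (the printed row average).
#' @export
envelope_width_reference <- function() {
  path <- system.file("extdata", "envelope_widths_reference.csv",
                      package = "sporesort", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
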