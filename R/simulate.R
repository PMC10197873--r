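# Synthetic data generators with known ground truth.
#
# Spectra are modelled as baseline polynomial + sum of Gaussian/Lorentzian
# bands + seeded additive Gaussian noise. The phenotype presets place each
# resting-cell type's marker bands at the catalog positions; every cell
# preset shares a "cell band" at 1650 cm^-1 so it clears the cell gate
# against the medium preset, while only the endospore preset carries enough
# CaDPA signal to clear the endospore gate. Amplitudes are phenomenological
# stand-ins (no measured intensities exist to emulate); they are chosen once
# to satisfy the documented separability margins:
#   endospore preset:      P_CaDPA >= 1.3 (noiseless, max mode)
#   other cell presets:    P_CaDPA <= 0.9
#   every cell preset:     Pc >= 1.5 against the medium preset
#   debris preset:         Pc <= 0.5
# All generators are pure functions of (model, seed).

PRESET_TAGS <- c("endospore", "vegetative_firmicute", "exospore", "myxospore",
                 "cyst", "akinete", "akinete_vegetative", "medium", "debris")

#' A synthetic spectral band
#'
#' @param center Band center, cm^-1.
#' @param amplitude Peak amplitude, a.u. (>= 0).
#' @param fwhm Full width at half maximum, cm^-1 (> 0).
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @return Object of class `peak_spec`.
#' @export
peak_spec <- function(center, amplitude, fwhm = 15,
                      shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  stopifnot_scalar_number(center, "center")
  stopifnot_scalar_number(amplitude, "amplitude")
  stopifnot_scalar_number(fwhm, "fwhm", positive = TRUE)
  if (amplitude < 0)
    ss_abort("amplitude must be >= 0", "sporesort_validation")
  structure(list(center = as.double(center), amplitude = as.double(amplitude),
                 fwhm = as.double(fwhm), shape = shape),
            class = "peak_spec")
}

eval_peak <- function(peak, wn) {
  if (peak$shape == "gaussian") {
    peak$amplitude * exp(-4 * log(2) * (wn - peak$center)^2 / peak$fwhm^2)
  } else {
    hw2 <- (peak$fwhm / 2)^2
    peak$amplitude * hw2 / ((wn - peak$center)^2 + hw2)
  }
}

#' A synthetic spectrum model
#'
#' @param peaks List of [peak_spec] objects.
#' @param baseline Polynomial coefficients `c(b0, b1, b2)` over wavenumber
#'   (degree <= 2; shorter vectors are zero-padded).
#' @param noise_sd Additive Gaussian noise standard deviation, a.u. (>= 0).
#'   Default 0.12, i.e. 2% of the largest preset band amplitude.
#' @param axis List `list(lo, hi, step)` in cm^-1; the default covers
#'   400-3300 cm^-1 at the 3.5 cm^-1 acquisition resolution.
#' @param phenotype Phenotype tag stored in generated spectra's metadata.
#' @param preset Preset tag (free text) recorded as ground truth.
#' @param seed Default RNG seed used by [generate_spectrum()].
#' @return Object of class `spectrum_model`.
#' @export
spectrum_model <- function(peaks = list(), baseline = 0, noise_sd = 0.12,
                           axis = list(lo = 400, hi = 3300, step = 3.5),
                           phenotype = "unknown", preset = NA_character_,
                           seed = 1L) {
  for (p in peaks)
    if (!inherits(p, "peak_spec"))
      ss_abort("peaks must be peak_spec objects", "sporesort_validation")
  baseline <- c(as.double(baseline), 0, 0)[1:3]
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) ss_abort("noise_sd must be >= 0", "sporesort_validation")
  stopifnot_scalar_number(axis$step, "axis$step", positive = TRUE)
  if (axis$lo >= axis$hi)
    ss_abort("axis lo must be < hi", "sporesort_validation")
  model <- structure(list(peaks = peaks, baseline = baseline,
                          noise_sd = as.double(noise_sd), axis = axis,
                          phenotype = phenotype,
                          preset = as.character(preset),
                          seed = as.integer(seed)),
                     class = "spectrum_model")
  wn <- model_axis(model)
  clean <- eval_model(model, wn)
  if (any(clean < 0))
    ss_abort("noiseless model evaluates negative on the axis",
             "sporesort_validation")
  model
}

model_axis <- function(model) seq(model$axis$lo, model$axis$hi,
                                  by = model$axis$step)

eval_model <- function(model, wn) {
  y <- model$baseline[1L] + model$baseline[2L] * wn + model$baseline[3L] * wn^2
  for (p in model$peaks) y <- y + eval_peak(p, wn)
  y
}

preset_table <- function() {
  cell_band <- function() peak_spec(1650, 2.0, 30)
  ch_band <- function(amp = 1.5) peak_spec(2900, amp, 60)
  list(
    endospore = list(
      phenotype = "endospore",
      peaks = list(peak_spec(1017, 2.0), peak_spec(1395, 6.0),
                   peak_spec(1446, 2.5), cell_band(), ch_band(1.0)),
      baseline = 0.8),
    vegetative_firmicute = list(
      phenotype = "vegetative",
      peaks = list(cell_band(), ch_band()),
      baseline = 0.8),
    exospore = list(
      phenotype = "exospore",
      # no CH2/CH3 band: absent from exospore spectra
      peaks = list(peak_spec(1342, 2.0), peak_spec(1586, 2.0), cell_band()),
      baseline = 0.8),
    myxospore = list(
      phenotype = "myxospore",
      peaks = list(peak_spec(1120, 1.5), peak_spec(1149, 1.5),
                   peak_spec(1550, 1.5), cell_band(), ch_band()),
      baseline = 0.8),
    cyst = list(
      phenotype = "cyst",
      peaks = list(peak_spec(830, 1.2), peak_spec(1150, 1.2),
                   peak_spec(1350, 1.2), cell_band(), ch_band()),
      baseline = 0.8),
    akinete = list(
      phenotype = "akinete",
      # carotenoid-dominated (resonance-enhanced) nu4/nu1 bands; no CH band
      peaks = list(peak_spec(1004, 2.5), peak_spec(1523, 3.5), cell_band()),
      baseline = 0.8),
    akinete_vegetative = list(
      phenotype = "vegetative",
      peaks = list(peak_spec(1004, 2.5), peak_spec(1523, 3.5), cell_band(),
                   peak_spec(2295, 1.0, 20)),
      baseline = 0.8),
    medium = list(
      phenotype = "medium",
      # 0.2 M glycerol background: flat with weak broad glycerol bands
      peaks = list(peak_spec(1460, 0.2, 30), peak_spec(2880, 0.3, 60)),
      baseline = 1.0),
    debris = list(
      phenotype = "debris",
      peaks = list(peak_spec(1100, 0.3, 40)),
      baseline = 0.4)
  )
}

#' Phenotype preset spectrum models
#'
#' @param tag One of `"endospore"`, `"vegetative_firmicute"`, `"exospore"`,
#'   `"myxospore"`, `"cyst"`, `"akinete"`, `"akinete_vegetative"`,
#'   `"medium"`, `"debris"`.
#' @param noise_sd,seed Passed to [spectrum_model()].
#' @return A [spectrum_model] carrying the phenotype's marker bands.
#' @examples
#' m <- phenotype_preset("endospore")
#' vapply(m$peaks, `[[`, numeric(1), "center")
#' @export
phenotype_preset <- function(tag, noise_sd = 0.12, seed = 1L) {
  tbl <- preset_table()
  if (!tag %in% names(tbl))
    ss_abort(sprintf("unknown preset tag '%s' (expected one of %s)", tag,
                     paste(names(tbl), collapse = ", ")),
             "sporesort_preset_miss")
  spec <- tbl[[tag]]
  spectrum_model(peaks = spec$peaks, baseline = spec$baseline,
                 noise_sd = noise_sd, phenotype = spec$phenotype,
                 preset = tag, seed = seed)
}

#' Generate a spectrum from a model
#'
#' Intensities are the noiseless model evaluation plus seeded Gaussian noise;
#' deterministic for a fixed seed, and the caller's RNG state is untouched.
#'
#' @param model A [spectrum_model].
#' @param seed Optional seed overriding `model$seed`.
#' @param label Label stored in the spectrum metadata.
#' @param amplitude_scale Multiplier applied to all band amplitudes (not the
#'   baseline); used by [generate_population()] to emulate cell-to-cell
#'   signal-strength variation.
#' @return A [raman_spectrum] with the model's phenotype and preset tags in
#'   its metadata.
#' @export
generate_spectrum <- function(model, seed = NULL, label = "",
                              amplitude_scale = 1) {
  if (!inherits(model, "spectrum_model"))
    ss_abort("expected a spectrum_model", "sporesort_validation")
  stopifnot_scalar_number(amplitude_scale, "amplitude_scale", positive = TRUE)
  seed <- as.integer(seed %||% model$seed)
  wn <- model_axis(model)
  scaled <- model
  scaled$peaks <- lapply(model$peaks, function(p) {
    p$amplitude <- p$amplitude * amplitude_scale
    p
  })
  y <- eval_model(scaled, wn)
  if (model$noise_sd > 0)
    y <- y + eval_with_seed(seed, stats::rnorm(length(wn), 0, model$noise_sd))
  raman_spectrum(wn, y, label = label, phenotype = model$phenotype,
                 meta = list(preset = model$preset, simulated = TRUE,
                             seed = seed))
}

#' Generate a labelled synthetic population
#'
#' Draws, per spectrum, a lognormal amplitude multiplier with mean 1 and the
#' given relative standard deviation (emulating the several-fold
#' cell-to-cell variation of marker-band intensity seen between strains and
#' individual cells), then generates each spectrum on its own RNG sub-stream
#' derived from the root seed by a stable counter - so membership order does
#' not alter individual spectra.
#'
#' @param counts Named integer vector: spectra per preset tag, e.g.
#'   `c(endospore = 20, vegetative_firmicute = 20)`.
#' @param jitter Relative standard deviation of the amplitude multiplier
#'   (default 0.1; 0 disables jitter).
#' @param seed Root seed.
#' @param noise_sd Noise level passed to every preset.
#' @return A [raman_collection]; each spectrum's metadata records its ground
#'   truth `preset` tag, and labels are `"<preset>_<i>"`.
#' @export
generate_population <- function(counts, jitter = 0.1, seed = 1L,
                                noise_sd = 0.12) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    ss_abort("counts must be a named vector of preset tags",
             "sporesort_validation")
  if (anyNA(counts) || any(counts < 0))
    ss_abort("counts must be >= 0", "sporesort_validation")
  stopifnot_scalar_number(jitter, "jitter")
  if (jitter < 0) ss_abort("jitter must be >= 0", "sporesort_validation")
  sdlog <- sqrt(log(1 + jitter^2))
  spectra <- list()
  counter <- 0L
  for (tag in names(counts)) {
    model <- phenotype_preset(tag, noise_sd = noise_sd)
    for (i in seq_len(counts[[tag]])) {
      counter <- counter + 1L
      s_seed <- derive_seed(seed, counter)
      mult <- if (jitter > 0)
        eval_with_seed(s_seed + 1L,
                       stats::rlnorm(1L, meanlog = -sdlog^2 / 2,
                                     sdlog = sdlog))
      else 1
      spectra[[counter]] <- generate_spectrum(
        model, seed = s_seed, label = sprintf("%s_%d", tag, i),
        amplitude_scale = mult)
    }
  }
  raman_collection(spectra)
}

#' Ground-truth preset tags of a generated population
#'
#' @param collection A [raman_collection] from [generate_population()].
#' @return Character vector of per-spectrum preset tags (`NA` for spectra
#'   without ground truth).
#' @export
population_truth <- function(collection) {
  vapply(collection, function(s) s$meta$preset %||% NA_character_,
         character(1L))
}

# --- synthetic envelope images ---------------------------------------------

#' A synthetic band-image model
#'
#' A straight dark (or bright) band of known physical width on a uniform
#' background, rendered with area-coverage anti-aliasing, Gaussian blur and
#' seeded noise. Emulates a cell envelope crossing an electron micrograph.
#'
#' @param width_nm True band width in nm (> 0).
#' @param size Image size in pixels, `c(nx, ny)`.
#' @param pixel_size_nm nm per pixel.
#' @param angle_deg Rotation of the band axis from vertical, degrees
#'   (0 = vertical band; positive rotates the band axis towards +x).
#' @param band_grey,background_grey Grey values of band and background; must
#'   differ.
#' @param blur_sigma_nm Gaussian blur sigma in nm (>= 0); default 8,
#'   emulating the point-spread/defocus softening of envelope edges.
#' @param noise_sd Additive Gaussian noise sd in grey units; default 5% of
#'   the band/background contrast.
#' @param seed RNG seed for the noise.
#' @return Object of class `band_image_model`.
#' @export
band_image_model <- function(width_nm, size = c(256L, 256L), pixel_size_nm = 2,
                             angle_deg = 0, band_grey = 60,
                             background_grey = 160, blur_sigma_nm = 8,
                             noise_sd = NULL, seed = 1L) {
  stopifnot_scalar_number(width_nm, "width_nm", positive = TRUE)
  stopifnot_scalar_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  stopifnot_scalar_number(blur_sigma_nm, "blur_sigma_nm")
  if (blur_sigma_nm < 0)
    ss_abort("blur_sigma_nm must be >= 0", "sporesort_validation")
  if (band_grey == background_grey)
    ss_abort("band_grey must differ from background_grey",
             "sporesort_validation")
  noise_sd <- noise_sd %||% (0.05 * abs(band_grey - background_grey))
  size <- as.integer(size)
  width_px <- width_nm / pixel_size_nm
  support <- width_px + 8 * blur_sigma_nm / pixel_size_nm
  if (support > min(size) * 0.9)
    ss_abort(sprintf(
      "band of %g nm (plus blur support) does not fit a %d x %d image at %g nm/px",
      width_nm, size[1L], size[2L], pixel_size_nm), "sporesort_geometry")
  structure(list(width_nm = as.double(width_nm), size = size,
                 pixel_size_nm = as.double(pixel_size_nm),
                 angle_deg = as.double(angle_deg),
                 band_grey = as.double(band_grey),
                 background_grey = as.double(background_grey),
                 blur_sigma_nm = as.double(blur_sigma_nm),
                 noise_sd = as.double(noise_sd), seed = as.integer(seed)),
            class = "band_image_model")
}

# Separable Gaussian convolution with replicate padding.
gaussian_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  r <- ceiling(4 * sigma_px)
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  conv_rows <- function(m) {
    nc <- ncol(m)
    pad <- cbind(m[, rep(1L, r), drop = FALSE], m,
                 m[, rep(nc, r), drop = FALSE])
    out <- matrix(0, nrow(m), nc)
    for (j in seq_along(k))
      out <- out + k[j] * pad[, j:(j + nc - 1L), drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(mat))))
}

#' Generate a synthetic band image
#'
#' @param model A [band_image_model].
#' @return Object of class `band_image`: list with `image` (a [grey_image])
#'   and `truth` (list: `width_nm`, `width_px`, `center` in pixel
#'   coordinates, `angle_deg`, `blur_sigma_nm`, `noise_sd`, `band_grey`,
#'   `background_grey`).
#' @export
generate_band_image <- function(model) {
  if (!inherits(model, "band_image_model"))
    ss_abort("expected a band_image_model", "sporesort_validation")
  nx <- model$size[1L]
  ny <- model$size[2L]
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  th <- model$angle_deg * pi / 180
  xs <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ys <- matrix(seq_len(ny), ny, nx)
  # signed perpendicular distance (px) from the band centerline
  dist <- (xs - cx) * cos(th) - (ys - cy) * sin(th)
  hw <- model$width_nm / model$pixel_size_nm / 2
  # area-coverage anti-aliasing along the perpendicular: fraction of the
  # 1-px-wide pixel interval covered by the band
  coverage <- pmin(dist + 0.5, hw) - pmax(dist - 0.5, -hw)
  coverage <- pmin(pmax(coverage, 0), 1)
  px <- model$background_grey +
    (model$band_grey - model$background_grey) * coverage
  px <- gaussian_blur(px, model$blur_sigma_nm / model$pixel_size_nm)
  if (model$noise_sd > 0)
    px <- px + eval_with_seed(model$seed,
                              matrix(stats::rnorm(nx * ny, 0, model$noise_sd),
                                     ny, nx))
  structure(list(
    image = grey_image(px, model$pixel_size_nm),
    truth = list(width_nm = model$width_nm,
                 width_px = model$width_nm / model$pixel_size_nm,
                 center = c(cx, cy), angle_deg = model$angle_deg,
                 blur_sigma_nm = model$blur_sigma_nm,
                 noise_sd = model$noise_sd, band_grey = model$band_grey,
                 background_grey = model$background_grey)),
    class = "band_image")
}

#' Profile line across a generated band
#'
#' Builds a [profile_line] through the band center, perpendicular to the
#' band axis, long enough to include baseline regions on both sides.
#'
#' @param band A `band_image` from [generate_band_image()].
#' @param half_length_px Half-length of the line in pixels; default covers
#'   the band plus blur support plus a 25 px baseline margin, clipped to the
#'   image.
#' @param averaging_width Passed to [profile_line()].
#' @return A [profile_line].
#' @export
band_profile_line <- function(band, half_length_px = NULL,
                              averaging_width = 23) {
  tr <- band$truth
  px <- band$image$pixels
  th <- tr$angle_deg * pi / 180
  normal <- c(cos(th), -sin(th))
  if (is.null(half_length_px)) {
    need <- tr$width_px / 2 + 4 * tr$blur_sigma_nm / band$image$pixel_size_nm + 25
    margin <- (averaging_width - 1) / 2 + 1
    lim <- min(ncol(px), nrow(px)) / 2 - margin
    half_length_px <- min(need, lim)
  }
  profile_line(tr$center - half_length_px * normal,
               tr$center + half_length_px * normal,
               averaging_width = averaging_width)
}
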