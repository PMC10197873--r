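# The Spectrum container: a Raman shift axis (cm^-1) with paired intensities
# (arbitrary detector units) and acquisition metadata. All spectral
# computation in the package operates on this class.

#' Recognized phenotype tags
#'
#' The resting-cell phenotypes covered by the marker catalog and the sorting
#' gate, plus bookkeeping tags for the suspension medium, debris particles and
#' unannotated spectra.
#'
#' @export
PHENOTYPE_TAGS <- c("vegetative", "endospore", "exospore", "myxospore",
                    "cyst", "akinete", "medium", "debris", "unknown")

#' Construct a single-cell Raman spectrum
#'
#' @param wavenumber Numeric vector of Raman shifts in cm^-1. Stored sorted
#'   ascending; a descending axis is silently canonicalized (some
#'   spectrometers export high-to-low shifts). Duplicated shifts are an error.
#' @param intensity Numeric vector of intensities (arbitrary units), same
#'   length as `wavenumber`. Negative values are permitted (raw detector
#'   offsets) but flagged in the metadata as `has_negative`.
#' @param label Free-text label for the cell/measurement.
#' @param phenotype One of [PHENOTYPE_TAGS].
#' @param laser_power_mw Laser power in mW (optional).
#' @param exposure_s Exposure time in seconds (optional).
#' @param strain Strain identifier (optional).
#' @param meta Additional metadata fields (named list); unknown keys are
#'   preserved verbatim through file round trips.
#'
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumber`, `intensity` and `meta`.
#' @examples
#' s <- raman_spectrum(c(800, 801, 802), c(1, 3, 5), label = "demo")
#' s$intensity
#' @export
raman_spectrum <- function(wavenumber, intensity, label = "",
                           phenotype = "unknown", laser_power_mw = NA_real_,
                           exposure_s = NA_real_, strain = NA_character_,
                           meta = list()) {
  if (!is.numeric(wavenumber) || !is.numeric(intensity))
    ss_abort("wavenumber and intensity must be numeric", "sporesort_validation")
  wavenumber <- as.double(wavenumber)
  intensity <- as.double(intensity)
  if (length(wavenumber) != length(intensity))
    ss_abort(sprintf("axis/intensity length mismatch (%d vs %d)",
                     length(wavenumber), length(intensity)),
             "sporesort_validation")
  if (length(wavenumber) < 1L)
    ss_abort("a spectrum needs at least one sample", "sporesort_validation")
  if (anyNA(wavenumber) || any(!is.finite(wavenumber)))
    ss_abort("wavenumbers must be finite", "sporesort_validation")
  if (anyNA(intensity) || any(!is.finite(intensity)))
    ss_abort("intensities must be finite", "sporesort_validation")
  ord <- order(wavenumber)
  wavenumber <- wavenumber[ord]
  intensity <- intensity[ord]
  if (anyDuplicated(wavenumber))
    ss_abort(sprintf("duplicated wavenumber %g cm^-1",
                     wavenumber[duplicated(wavenumber)][1L]),
             "sporesort_validation")
  if (!phenotype %in% PHENOTYPE_TAGS)
    ss_abort(sprintf("unknown phenotype tag '%s'", phenotype),
             "sporesort_validation")
  base_meta <- list(label = as.character(label), phenotype = phenotype,
                    laser_power_mw = as.double(laser_power_mw),
                    exposure_s = as.double(exposure_s),
                    strain = as.character(strain))
  meta <- utils::modifyList(base_meta, as.list(meta))
  meta$has_negative <- any(intensity < 0)
  structure(list(wavenumber = wavenumber, intensity = intensity, meta = meta),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d samples, %.1f-%.1f cm^-1\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  cat(sprintf("  label: '%s'  phenotype: %s%s\n", x$meta$label,
              x$meta$phenotype,
              if (isTRUE(x$meta$normalized)) "  (min-max normalized)" else ""))
  invisible(x)
}

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumber, intensity = x$intensity)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumber)

is_raman_spectrum <- function(x) inherits(x, "raman_spectrum")

assert_spectrum <- function(x, name = "spectrum") {
  if (!is_raman_spectrum(x))
    ss_abort(sprintf("'%s' must be a raman_spectrum", name),
             "sporesort_validation")
  invisible(x)
}

#' Construct an ordered collection of spectra
#'
#' A collection groups the 15-20 individual cells typically measured per
#' sample. The shared-axis flag is computed, not asserted: it is `TRUE` only
#' when every member has an element-wise identical wavenumber axis.
#'
#' @param spectra List of [raman_spectrum] objects.
#' @return Object of class `raman_collection` (a list of spectra with a
#'   `shared_axis` attribute).
#' @export
raman_collection <- function(spectra = list()) {
  if (is_raman_spectrum(spectra)) spectra <- list(spectra)
  for (s in spectra) assert_spectrum(s)
  shared <- length(spectra) <= 1L ||
    all(vapply(spectra[-1L],
               function(s) identical(s$wavenumber, spectra[[1L]]$wavenumber),
               logical(1L)))
  structure(spectra, shared_axis = shared, class = "raman_collection")
}

#' @export
print.raman_collection <- function(x, ...) {
  cat(sprintf("<raman_collection> %d spectra, shared axis: %s\n",
              length(x), attr(x, "shared_axis")))
  invisible(x)
}

#' Labels of a spectrum collection
#' @param collection A [raman_collection].
#' @return Character vector of per-spectrum labels.
#' @export
collection_labels <- function(collection) {
  vapply(collection, function(s) s$meta$label, character(1L))
}
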