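# Phenotype-specific Raman marker bands and signature scoring.
#
# The catalog records the bands that distinguish each specialized resting
# cell from its vegetative counterpart: the calcium dipicolinate (CaDPA)
# triplet for endospores, two amino-acid bands for exospores, the trehalose
# doublet plus a third band for myxospores, three bands (one of them
# trehalose) for cysts, and one band present only in vegetative cyanobacteria
# filaments. The near-universal ~2900 cm^-1 CH2/CH3 stretch is carried under
# the generic "vegetative" tag: it marks cellular material but does not
# discriminate the resting-cell types, so it is deliberately kept out of the
# five spore-type signature sets.

#' Construct a marker peak
#'
#' @param center Band center, cm^-1, inside (0, 4000).
#' @param half_window Matching half-window in cm^-1 (default 10: roughly 3x
#'   the 3.5 cm^-1 spectral resolution of the acquisitions the catalog was
#'   drawn from, wide enough to absorb the 1443-vs-1446 style variation seen
#'   between repeated band readings).
#' @param assignment Free-text chemical assignment (e.g. "CaDPA").
#' @param phenotypes Character vector of phenotype tags the band marks;
#'   must be non-empty.
#' @return Object of class `marker_peak`.
#' @export
marker_peak <- function(center, half_window = 10, assignment = "",
                        phenotypes = character()) {
  stopifnot_scalar_number(center, "center")
  stopifnot_scalar_number(half_window, "half_window", positive = TRUE)
  if (center <= 0 || center >= 4000)
    ss_abort("marker center must lie inside (0, 4000) cm^-1",
             "sporesort_validation")
  phenotypes <- as.character(phenotypes)
  if (length(phenotypes) == 0L)
    ss_abort("a marker peak needs at least one phenotype tag",
             "sporesort_validation")
  structure(list(center = as.double(center),
                 half_window = as.double(half_window),
                 assignment = as.character(assignment),
                 phenotypes = phenotypes),
            class = "marker_peak")
}

#' Construct a marker catalog
#'
#' @param peaks List of [marker_peak] objects. No two entries may share both
#'   the center and the phenotype set.
#' @return Object of class `marker_catalog`.
#' @export
marker_catalog <- function(peaks) {
  for (p in peaks)
    if (!inherits(p, "marker_peak"))
      ss_abort("all catalog entries must be marker_peak objects",
               "sporesort_validation")
  key <- vapply(peaks, function(p)
    paste(p$center, paste(sort(p$phenotypes), collapse = "|")), character(1L))
  if (anyDuplicated(key))
    ss_abort("duplicate (center, phenotypes) catalog entry",
             "sporesort_validation")
  structure(list(peaks = peaks), class = "marker_catalog")
}

#' @export
print.marker_catalog <- function(x, ...) {
  cat(sprintf("<marker_catalog> %d peaks\n", length(x$peaks)))
  for (p in x$peaks)
    cat(sprintf("  %7.1f cm^-1 +/-%g  %-28s %s\n", p$center, p$half_window,
                p$assignment, paste(p$phenotypes, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.marker_catalog <- function(x, ...) {
  data.frame(
    center = vapply(x$peaks, `[[`, numeric(1L), "center"),
    half_window = vapply(x$peaks, `[[`, numeric(1L), "half_window"),
    assignment = vapply(x$peaks, `[[`, character(1L), "assignment"),
    phenotypes = vapply(x$peaks, function(p)
      paste(p$phenotypes, collapse = ";"), character(1L)),
    stringsAsFactors = FALSE)
}

#' The built-in marker-band catalog
#'
#' Band positions (cm^-1) and assignments:
#' * endospore: 1017, 1395, 1446 - calcium dipicolinate (CaDPA); the 1446
#'   band has also been read as 1443 in repeat measurements, covered by the
#'   10 cm^-1 matching half-window.
#' * exospore: 1342, 1586 - amino-acid bands (likely L-glutamate and
#'   L-phenylalanine).
#' * myxospore: 1120, 1149 (trehalose) and 1550; an alternative reading of
#'   the third band at 1505 is retained under the tag `myxospore_alt` so the
#'   primary signature stays the three-band set.
#' * cyst: 830 (trehalose), 1150, 1350.
#' * akinete_vegetative: 2295 - present in vegetative cyanobacterial
#'   filaments and absent in akinetes (the discrimination runs the other way
#'   round for this phenotype).
#' * vegetative: ~2900 - CH2/CH3 stretch, present in nearly all cell spectra
#'   (a notable exception being exospores) and therefore non-discriminating;
#'   stored with a wider half-window because the band is broad.
#'
#' @return A [marker_catalog].
#' @export
default_catalog <- function() {
  marker_catalog(list(
    marker_peak(1017, 10, "CaDPA", "endospore"),
    marker_peak(1395, 10, "CaDPA", "endospore"),
    marker_peak(1446, 10, "CaDPA (also read as 1443)", "endospore"),
    marker_peak(1342, 10, "amino acid (L-glutamate)", "exospore"),
    marker_peak(1586, 10, "amino acid (L-phenylalanine)", "exospore"),
    marker_peak(1120, 10, "trehalose", "myxospore"),
    marker_peak(1149, 10, "trehalose", "myxospore"),
    marker_peak(1550, 10, "myxospore band", "myxospore"),
    marker_peak(1505, 10, "alternative reading of the 1550 myxospore band",
                "myxospore_alt"),
    marker_peak(830, 10, "trehalose", "cyst"),
    marker_peak(1150, 10, "cyst band", "cyst"),
    marker_peak(1350, 10, "cyst band", "cyst"),
    marker_peak(2295, 10, "vegetative-only cyanobacterial band",
                "akinete_vegetative"),
    marker_peak(2900, 25, "CH2/CH3 stretch (broad, non-discriminating)",
                "vegetative")
  ))
}

#' Write / read a marker catalog as CSV
#'
#' One peak per row: `center, half_window, assignment, phenotypes`
#' (phenotypes `;`-separated), so users can extend the catalog in a text
#' editor.
#'
#' @param catalog A [marker_catalog].
#' @param path File path.
#' @return `write_catalog`: the path invisibly; `read_catalog`: a
#'   [marker_catalog].
#' @export
write_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  lines <- c("center,half_window,assignment,phenotypes",
             sprintf("%s,%s,\"%s\",%s", format_num(df$center),
                     format_num(df$half_window), df$assignment, df$phenotypes))
  invisible(write_atomic(lines, path))
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  marker_catalog(lapply(seq_len(nrow(df)), function(i)
    marker_peak(df$center[i], df$half_window[i], df$assignment[i],
                strsplit(df$phenotypes[i], ";", fixed = TRUE)[[1L]])))
}

# Topographic prominence of the local maximum at index i: on each side, walk
# to the nearest strictly higher sample (or the series end) tracking the
# minimum; the peak's base is the higher of the two side minima.
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]
  j <- i - 1L
  while (j >= 1L && y[j] <= y[i]) {
    if (y[j] < left_min) left_min <- y[j]
    j <- j - 1L
  }
  right_min <- y[i]
  j <- i + 1L
  while (j <= n && y[j] <= y[i]) {
    if (y[j] < right_min) right_min <- y[j]
    j <- j + 1L
  }
  y[i] - max(left_min, right_min)
}

#' Detect peaks in a spectrum
#'
#' Local maxima whose topographic prominence reaches `min_prominence` times
#' the spectrum's intensity range, greedily thinned so no two retained peaks
#' lie closer than `min_separation` cm^-1 (the taller peak wins). Expressing
#' the prominence threshold as a fraction of the range makes detection
#' invariant under positive rescaling of the intensities.
#'
#' @param spectrum A [raman_spectrum] with at least 3 samples.
#' @param min_prominence Prominence threshold as a fraction of the intensity
#'   range (default 0.05).
#' @param min_separation Minimum separation between retained peaks, cm^-1
#'   (default 8).
#' @return A data.frame with columns `position` (cm^-1), `height` (a.u.) and
#'   `prominence` (a.u.), sorted by position; zero rows when nothing is
#'   detected.
#' @export
detect_peaks <- function(spectrum, min_prominence = 0.05, min_separation = 8) {
  assert_spectrum(spectrum)
  if (length(spectrum$wavenumber) < 3L)
    ss_abort("peak detection needs at least 3 samples", "sporesort_validation")
  y <- spectrum$intensity
  x <- spectrum$wavenumber
  n <- length(y)
  empty <- data.frame(position = numeric(), height = numeric(),
                      prominence = numeric())
  rng <- max(y) - min(y)
  if (rng <= 0) return(empty)
  cand <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] > y[3:n]) + 1L
  if (length(cand) == 0L) return(empty)
  prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1L))
  keep <- prom >= min_prominence * rng
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) == 0L) return(empty)
  ord <- order(y[cand], -x[cand], decreasing = TRUE)
  kept <- integer()
  for (k in ord) {
    if (all(abs(x[cand[k]] - x[cand[kept]]) >= min_separation))
      kept <- c(kept, k)
  }
  kept <- kept[order(x[cand[kept]])]
  data.frame(position = x[cand[kept]], height = y[cand[kept]],
             prominence = prom[kept])
}

catalog_peaks_for <- function(catalog, phenotype) {
  if (!inherits(catalog, "marker_catalog"))
    ss_abort("expected a marker_catalog", "sporesort_validation")
  hits <- Filter(function(p) phenotype %in% p$phenotypes, catalog$peaks)
  if (length(hits) == 0L)
    ss_abort(sprintf("phenotype '%s' has no peaks in the catalog", phenotype),
             "sporesort_catalog_miss")
  hits
}

#' Score a spectrum against a phenotype's marker signature
#'
#' The fraction of the phenotype's catalog bands matched by a detected peak
#' within the band's matching half-window. Invariant under positive rescaling
#' of the intensities (the detection threshold is range-relative); adding
#' unrelated peaks can only keep or raise a score, never lower it.
#'
#' @inheritParams detect_peaks
#' @param phenotype Phenotype tag present in the catalog.
#' @param catalog A [marker_catalog]; defaults to [default_catalog()].
#' @return Fraction in \[0, 1\].
#' @export
signature_score <- function(spectrum, phenotype, catalog = default_catalog(),
                            min_prominence = 0.05, min_separation = 8) {
  peaks <- catalog_peaks_for(catalog, phenotype)
  detected <- detect_peaks(spectrum, min_prominence, min_separation)
  if (nrow(detected) == 0L) return(0)
  matched <- vapply(peaks, function(p)
    any(abs(detected$position - p$center) <= p$half_window), logical(1L))
  mean(matched)
}
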