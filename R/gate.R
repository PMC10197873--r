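# The two-threshold sorting gate.
#
# Stage 1 separates cells from debris with the cell statistic
#   Pc = integral of cell intensity over the cell window (default
#        1620-1670 cm^-1) / same integral of the suspension-medium spectrum,
# a region that is specific to cellular material without corresponding to a
# single molecular bond. Particles with Pc below the cell threshold
# (default 1) go to waste.
#
# Stage 2 separates endospores from vegetative cells with the CaDPA
# statistic
#   P_CaDPA = statistic of the CaDPA window (default 1370-1420 cm^-1) /
#             statistic of the cell window, both on the SAME cell spectrum,
# where the statistic is the in-window maximum (default) or the integrated
# intensity. Cells at or above the endospore threshold (default 1.1, chosen
# conservatively so that only unambiguous CaDPA carriers are routed to the
# endospore compartment) are called endospores.
#
# Both statistics are computed on raw (un-normalized) intensities: the
# cell/medium ratio is only meaningful when both spectra share the detector
# scale, which per-spectrum min-max normalization would destroy.
#
# Boundary ties: ">= threshold" passes each gate, so a particle identical to
# the medium (Pc exactly 1) is analysed rather than discarded.

#' Gate thresholds
#'
#' @param pc_threshold Cell threshold on Pc (default 1).
#' @param pcadpa_threshold Endospore threshold on P_CaDPA (default 1.1).
#' @return Object of class `gate_thresholds`.
#' @export
gate_thresholds <- function(pc_threshold = 1, pcadpa_threshold = 1.1) {
  stopifnot_scalar_number(pc_threshold, "pc_threshold", positive = TRUE)
  stopifnot_scalar_number(pcadpa_threshold, "pcadpa_threshold", positive = TRUE)
  structure(list(pc_threshold = as.double(pc_threshold),
                 pcadpa_threshold = as.double(pcadpa_threshold)),
            class = "gate_thresholds")
}

#' Gate windows
#'
#' @param cell_window Cell region, default `spectral_window(1620, 1670)`.
#' @param cadpa_window CaDPA region, default `spectral_window(1370, 1420)`.
#'   Must lie entirely below the cell window.
#' @return Object of class `gate_windows`.
#' @export
gate_windows <- function(cell_window = spectral_window(1620, 1670),
                         cadpa_window = spectral_window(1370, 1420)) {
  assert_window(cell_window)
  assert_window(cadpa_window)
  if (cadpa_window$hi >= cell_window$lo)
    ss_abort("cadpa_window must lie entirely below cell_window",
             "sporesort_validation")
  structure(list(cell_window = cell_window, cadpa_window = cadpa_window),
            class = "gate_windows")
}

# Integrate both spectra over `window` on the cell's window knots (in-window
# samples plus interpolated window edges), resampling the medium onto those
# knots when the axes differ.
paired_window_integrals <- function(cell, medium, window) {
  k <- window_knots(cell, window)
  if (k$n_samples < 2L)
    ss_abort("cell spectrum does not cover the cell window",
             "sporesort_insufficient_samples")
  med_vals <- if (identical(medium$wavenumber, cell$wavenumber)) {
    stats::approx(medium$wavenumber, medium$intensity, xout = k$x,
                  method = "linear", ties = "ordered")$y
  } else {
    if (min(k$x) < min(medium$wavenumber) || max(k$x) > max(medium$wavenumber))
      ss_abort("medium spectrum does not cover the cell window",
               "sporesort_out_of_span")
    stats::approx(medium$wavenumber, medium$intensity, xout = k$x,
                  method = "linear", ties = "ordered")$y
  }
  c(cell = pracma::trapz(k$x, k$y),
    medium = pracma::trapz(k$x, med_vals))
}

#' Cell statistic Pc
#'
#' Ratio of the integrated cell-window intensity of a measured particle to
#' that of the suspension medium, both on raw intensities. Homogeneous in the
#' cell spectrum: scaling the particle intensities by a > 0 scales Pc by a.
#'
#' @param cell Measured particle [raman_spectrum] (cell, spore or debris).
#' @param medium Medium/background [raman_spectrum] acquired under the same
#'   settings; resampled (linearly) onto the cell axis when the axes differ.
#' @param windows A [gate_windows].
#' @return Scalar Pc ratio.
#' @export
compute_pc <- function(cell, medium, windows = gate_windows()) {
  assert_spectrum(cell, "cell")
  assert_spectrum(medium, "medium")
  ints <- paired_window_integrals(cell, medium, windows$cell_window)
  if (ints[["medium"]] <= 0)
    ss_abort("medium integral over the cell window is not positive",
             "sporesort_invalid_reference")
  unname(ints[["cell"]] / ints[["medium"]])
}

#' Endospore statistic P_CaDPA
#'
#' Ratio of the CaDPA-window statistic to the cell-window statistic of one
#' spectrum. Scale-invariant: multiplying the intensities by a > 0 leaves the
#' ratio unchanged (both modes).
#'
#' @param cell Measured cell [raman_spectrum].
#' @param windows A [gate_windows].
#' @param mode `"max"` (default; ratio of in-window maxima) or
#'   `"integrated"` (ratio of trapezoidal integrals).
#' @return Scalar P_CaDPA ratio.
#' @export
compute_pcadpa <- function(cell, windows = gate_windows(),
                           mode = c("max", "integrated")) {
  assert_spectrum(cell, "cell")
  mode <- match.arg(mode)
  stat <- if (mode == "max") max_in_window else integrate_window
  denom <- stat(cell, windows$cell_window)
  if (denom <= 0)
    ss_abort("cell-window statistic is not positive", "sporesort_invalid_denominator")
  stat(cell, windows$cadpa_window) / denom
}

#' Classify one measured particle
#'
#' Stage 1: `Pc < pc_threshold` routes to `"waste"` (P_CaDPA not computed).
#' Stage 2: `P_CaDPA >= pcadpa_threshold` routes to `"endospore"`, otherwise
#' `"vegetative"`.
#'
#' @inheritParams compute_pc
#' @param thresholds A [gate_thresholds].
#' @inheritParams compute_pcadpa
#' @return Object of class `sort_result`: list with `pc`, `pcadpa` (`NA`
#'   when routed to waste at stage 1), `decision` and `mode`.
#' @export
classify_spectrum <- function(cell, medium, thresholds = gate_thresholds(),
                              windows = gate_windows(),
                              mode = c("max", "integrated")) {
  mode <- match.arg(mode)
  pc <- compute_pc(cell, medium, windows)
  if (pc < thresholds$pc_threshold) {
    res <- list(pc = pc, pcadpa = NA_real_, decision = "waste", mode = mode)
  } else {
    pcadpa <- compute_pcadpa(cell, windows, mode)
    res <- list(pc = pc, pcadpa = pcadpa,
                decision = if (pcadpa >= thresholds$pcadpa_threshold)
                  "endospore" else "vegetative",
                mode = mode)
  }
  structure(res, class = "sort_result")
}

#' @export
print.sort_result <- function(x, ...) {
  cat(sprintf("<sort_result> Pc = %.4g, P_CaDPA = %s (%s mode) -> %s\n",
              x$pc, if (is.na(x$pcadpa)) "-" else sprintf("%.4g", x$pcadpa),
              x$mode, x$decision))
  invisible(x)
}

#' Classify a collection of spectra
#'
#' Applies [classify_spectrum()] to every member, order-preserving.
#' Per-spectrum failures are recorded as decision `"error"` (with the message
#' in the `note` column) without aborting the batch.
#'
#' @param cells A [raman_collection] (or list of spectra).
#' @inheritParams classify_spectrum
#' @return Object of class `sort_batch`: list with `results` (data.frame:
#'   `label`, `pc`, `pcadpa`, `decision`, `note`) and `counts` (named integer
#'   vector over waste/vegetative/endospore/error).
#' @export
batch_classify <- function(cells, medium, thresholds = gate_thresholds(),
                           windows = gate_windows(),
                           mode = c("max", "integrated")) {
  mode <- match.arg(mode)
  if (!inherits(cells, "raman_collection")) cells <- raman_collection(cells)
  n <- length(cells)
  results <- data.frame(label = character(n), pc = rep(NA_real_, n),
                        pcadpa = rep(NA_real_, n), decision = character(n),
                        note = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- cells[[i]]
    results$label[i] <- s$meta$label
    out <- tryCatch(classify_spectrum(s, medium, thresholds, windows, mode),
                    sporesort_error = function(e) e)
    if (inherits(out, "sort_result")) {
      results$pc[i] <- out$pc
      results$pcadpa[i] <- out$pcadpa
      results$decision[i] <- out$decision
    } else {
      results$decision[i] <- "error"
      results$note[i] <- conditionMessage(out)
    }
  }
  lev <- c("waste", "vegetative", "endospore", "error")
  counts <- table(factor(results$decision, levels = lev))
  structure(list(results = results,
                 counts = stats::setNames(as.integer(counts), lev),
                 mode = mode),
            class = "sort_batch")
}

#' @export
print.sort_batch <- function(x, ...) {
  cat(sprintf("<sort_batch> %d spectra (%s mode): %s\n", nrow(x$results),
              x$mode,
              paste(sprintf("%s %d", names(x$counts), x$counts),
                    collapse = ", ")))
  invisible(x)
}

#' Write batch classification results as CSV
#'
#' Columns `label, pc, pcadpa, decision` (plus `note` for error rows).
#'
#' @param batch A `sort_batch` from [batch_classify()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_sort_results <- function(batch, path) {
  df <- batch$results
  fmt <- function(v) ifelse(is.na(v), "", format_num(v))
  lines <- c("label,pc,pcadpa,decision,note",
             sprintf("%s,%s,%s,%s,%s", df$label, fmt(df$pc), fmt(df$pcadpa),
                     df$decision, df$note))
  invisible(write_atomic(lines, path))
}
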