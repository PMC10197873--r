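# Plain-text spectrum IO.
#
# Storage format: comma-separated values preceded by a '#'-prefixed metadata
# header block ("# key: value" lines). Two dialects:
#   two_column  header "wavenumber_cm-1,intensity", one spectrum per file;
#   wide_table  header "wavenumber_cm-1,<label1>,<label2>,...", a collection
#               sharing one axis, column names become spectrum labels.
# Numbers are stored with 12 significant digits, which the round-trip
# guarantee is quoted at.

META_KEYS <- c("label", "phenotype", "laser_power_mw", "exposure_s", "strain")

format_num <- function(x) sprintf("%.12g", x)

parse_meta_value <- function(v) {
  v <- trimws(v)
  if (v %in% c("true", "TRUE")) return(TRUE)
  if (v %in% c("false", "FALSE")) return(FALSE)
  if (v == "NA") return(NA)
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num) && grepl("^[-+0-9.eE]+$", v)) return(num)
  v
}

meta_header_lines <- function(meta) {
  meta <- meta[!vapply(meta, is.null, logical(1L))]
  meta$has_negative <- NULL  # derived; recomputed on read
  keys <- union(intersect(META_KEYS, names(meta)), names(meta))
  vapply(keys, function(k) {
    v <- meta[[k]]
    v <- if (is.logical(v)) tolower(as.character(v))
         else if (is.numeric(v)) format_num(v) else as.character(v)
    sprintf("# %s: %s", k, v)
  }, character(1L))
}

#' Write a spectrum (or collection) to a plain-text file
#'
#' @param spectrum A [raman_spectrum], or a [raman_collection] sharing one
#'   axis (written as a wide table with one intensity column per spectrum).
#' @param path Output file path. Written atomically (temp file + rename).
#' @return The path, invisibly.
#' @seealso [read_spectrum()] for the inverse; the round trip reproduces the
#'   axis, intensities (12 significant digits) and all metadata fields.
#' @export
write_spectrum <- function(spectrum, path) {
  if (inherits(spectrum, "raman_collection")) {
    if (!attr(spectrum, "shared_axis"))
      ss_abort("wide-table export needs a shared wavenumber axis",
               "sporesort_validation")
    if (length(spectrum) == 0L)
      ss_abort("cannot write an empty collection", "sporesort_validation")
    labels <- collection_labels(spectrum)
    if (any(labels == "")) labels[labels == ""] <-
        paste0("spectrum_", which(labels == ""))
    header <- paste(c("wavenumber_cm-1", labels), collapse = ",")
    mat <- vapply(spectrum, function(s) s$intensity,
                  numeric(length(spectrum[[1L]]$wavenumber)))
    rows <- apply(cbind(spectrum[[1L]]$wavenumber, mat), 1L,
                  function(r) paste(format_num(r), collapse = ","))
    return(invisible(write_atomic(c(header, rows), path)))
  }
  assert_spectrum(spectrum)
  lines <- c(meta_header_lines(spectrum$meta),
             "wavenumber_cm-1,intensity",
             paste(format_num(spectrum$wavenumber),
                   format_num(spectrum$intensity), sep = ","))
  invisible(write_atomic(lines, path))
}

parse_numeric_cells <- function(cells, row_numbers, path) {
  out <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(out) & !cells %in% "NA")
  if (length(bad))
    ss_abort(sprintf("non-numeric value '%s' at data row %d of '%s'",
                     cells[bad[1L]], row_numbers[bad[1L]], path),
             "sporesort_parse")
  out
}

#' Read a spectrum or spectrum collection from a plain-text file
#'
#' @param path File path.
#' @param dialect `"two_column"` (one spectrum), `"wide_table"` (first column
#'   wavenumber, one column per cell) or `"auto"` (decide by column count).
#' @return A [raman_spectrum] or, for wide tables, a [raman_collection] with
#'   the shared-axis flag set. The axis is canonicalized to ascending order
#'   regardless of storage order; row order in the file is immaterial.
#' @export
read_spectrum <- function(path, dialect = c("auto", "two_column", "wide_table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    ss_abort(sprintf("file '%s' does not exist", path), "sporesort_io")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_meta <- grepl("^\\s*#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) meta[[trimws(m[2L])]] <- parse_meta_value(m[3L])
  }
  body <- lines[!is_meta]
  if (length(body) < 3L)
    ss_abort(sprintf("'%s': need a header and at least two data rows", path),
             "sporesort_parse")
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  ncol <- length(header)
  if (ncol < 2L)
    ss_abort(sprintf("'%s': expected at least two columns", path),
             "sporesort_parse")
  if (dialect == "auto")
    dialect <- if (ncol == 2L) "two_column" else "wide_table"
  if (dialect == "two_column" && ncol != 2L)
    ss_abort(sprintf("'%s': two_column dialect needs exactly 2 columns, found %d",
                     path, ncol), "sporesort_parse")
  cells <- strsplit(body[-1L], ",", fixed = TRUE)
  lens <- lengths(cells)
  if (any(lens != ncol))
    ss_abort(sprintf("'%s': row %d has %d fields, expected %d", path,
                     which(lens != ncol)[1L], lens[lens != ncol][1L], ncol),
             "sporesort_parse")
  mat <- matrix(NA_real_, nrow = length(cells), ncol = ncol)
  for (j in seq_len(ncol))
    mat[, j] <- parse_numeric_cells(vapply(cells, `[[`, character(1L), j),
                                    seq_along(cells), path)
  wn <- mat[, 1L]
  if (anyDuplicated(wn))
    ss_abort(sprintf("'%s': duplicated wavenumber %g", path,
                     wn[duplicated(wn)][1L]), "sporesort_validation")
  std <- meta[intersect(META_KEYS, names(meta))]
  extra <- meta[setdiff(names(meta), META_KEYS)]
  make_one <- function(intensity, label) {
    do.call(raman_spectrum,
            c(list(wavenumber = wn, intensity = intensity),
              std[setdiff(names(std), if (label_override) "label" else character())],
              if (label_override) list(label = label),
              list(meta = extra)))
  }
  if (dialect == "two_column") {
    label_override <- FALSE
    make_one(mat[, 2L], NULL)
  } else {
    label_override <- TRUE
    raman_collection(lapply(seq_len(ncol - 1L), function(j)
      make_one(mat[, j + 1L], header[j + 1L])))
  }
}
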