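# Internal helpers shared across modules.

#' Signal a classed package error
#'
#' All user-facing failures in the package raise conditions that inherit from
#' `"sporesort_error"` plus a specific class (e.g. `"sporesort_empty_window"`),
#' so callers can branch on the failure mode instead of matching messages.
#'
#' @param msg Human-readable message.
#' @param class Specific condition class.
#' @noRd
ss_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sporesort_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with a fixed RNG seed, restoring the caller's RNG state.
eval_with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable per-item sub-stream seed derived from a root seed and a counter, so
# population membership order does not alter individual draws. Kept < 2^31-1.
derive_seed <- function(root, counter) {
  root <- abs(as.integer(root))
  as.integer((as.double(root %% 100000L) * 20011 + as.double(counter) * 7919) %%
               2147483629)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ss_abort(sprintf("'%s' must be a single finite number", name),
             "sporesort_validation")
  if (positive && x <= 0)
    ss_abort(sprintf("'%s' must be > 0", name), "sporesort_validation")
  invisible(x)
}

# Atomic text write: write to a sibling temp file, then rename over the target.
write_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path))
    ss_abort(sprintf("cannot write '%s'", path), "sporesort_io")
  invisible(path)
}
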