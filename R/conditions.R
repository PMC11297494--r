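#' @keywords internal
#' Classed conditions used across the package.
#'
#' Classes map onto CLI exit codes: validation errors -> 2, I/O errors -> 3,
#' degenerate-normalization errors -> 4, cache-format errors -> 2.

abort <- function(message, class) {
  stop(structure(
    class = c(class, "zernike3d_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

abort_validation <- function(message) abort(message, "zernike3d_validation_error")
abort_io <- function(message) abort(message, "zernike3d_io_error")
abort_degenerate <- function(message) abort(message, "zernike3d_degenerate_error")
abort_cache_format <- function(message) abort(message, "zernike3d_cache_format_error")

stopifnot_finite_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x) || any(!is.finite(x))) {
    abort_validation(sprintf("%s must be a finite numeric matrix", what))
  }
  invisible(x)
}
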