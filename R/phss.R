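#' Phase-shift subtraction
#'
#' Subtracts a record from itself shifted by exactly one scan revolution
#' (`steps_per_rev` samples, the period `T = 1/f_s` of the scanning
#' system): `y[n] = x[n] - x[(n - steps_per_rev) mod N]`. Everything that
#' repeats over one scan revolution -- the depolarized scan-synchronous
#' background, and the power line, which completes exactly two cycles per
#' revolution under synchronized sampling -- cancels identically, while
#' every component at an odd multiple of half the scan frequency is doubled
#' in amplitude. The transfer gain is `|1 - e^{-i 2 pi f / f_s}|`: 0 at
#' integer multiples of `f_s`, exactly 2 at half-integer multiples.
#'
#' The default shift is circular over the record, which is an exact
#' identity because each record spans an integer number of revolutions;
#' `circular = FALSE` emulates a streaming implementation and drops the
#' first revolution (output is `N - steps_per_rev` samples).
#'
#' @param x a `raw_record`, a numeric vector, or a channels-by-samples
#'   numeric matrix.
#' @param shift_samples shift in samples; defaults to `steps_per_rev` of
#'   the record's configuration (200).
#' @param circular logical, see Details.
#' @param ... passed between methods.
#' @return same shape as the input; for a `raw_record`, a `phss_record`.
#' @export
phss <- function(x, ...) UseMethod("phss")

phss_matrix <- function(m, shift, circular) {
  n <- ncol(m)
  if (circular) {
    if (n %% shift != 0) {
      stop("configuration error: record length is not an integer number of shift periods",
           call. = FALSE)
    }
    idx <- ((seq_len(n) - 1 - shift) %% n) + 1
    m - m[, idx, drop = FALSE]
  } else {
    m[, (shift + 1):n, drop = FALSE] - m[, 1:(n - shift), drop = FALSE]
  }
}

#' @rdname phss
#' @export
phss.default <- function(x, shift_samples = 200, circular = TRUE, ...) {
  stopifnot(is.numeric(x))
  if (is.matrix(x)) return(phss_matrix(x, shift_samples, circular))
  drop(phss_matrix(matrix(x, 1), shift_samples, circular))
}

#' @rdname phss
#' @export
phss.raw_record <- function(x, shift_samples = NULL, circular = TRUE, ...) {
  shift <- if (is.null(shift_samples)) x$cfg$steps_per_rev else shift_samples
  out <- x
  out$samples <- phss_matrix(x$samples, shift, circular)
  out$shift_samples <- shift
  class(out) <- c("phss_record", "raw_record")
  out
}

#' @export
print.phss_record <- function(x, ...) {
  cat("<phss_record> 4 x ", ncol(x$samples), " samples, shift ",
      x$shift_samples, "\n", sep = "")
  invisible(x)
}
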