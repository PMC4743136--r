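#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a threshold calibration
#'
#' @param x a `cf_threshold`.
#' @param ... unused.
#' @return one row per estimated quantity.
#' @method tidy cf_threshold
#' @export
tidy.cf_threshold <- function(x, ...) {
  tibble::tibble(term = "theta", estimate = x$theta)
}

#' @rdname tidy.cf_threshold
#' @method glance cf_threshold
#' @export
glance.cf_threshold <- function(x, ...) {
  tibble::tibble(theta = x$theta, objective = x$objective,
                 n_cf = x$n_cf, n_para = x$n_para,
                 total_error = if (!is.null(x$trace))
                   min(x$trace$total) else NA_real_)
}

#' Tidy a discriminant model
#'
#' Reports the explicit boundary coefficients `a0, a1, ...` (decision
#' variable last).
#'
#' @param x a `cf_lda`.
#' @param ... unused.
#' @method tidy cf_lda
#' @export
tidy.cf_lda <- function(x, ...) {
  tibble::tibble(term = names(x$a), estimate = as.numeric(x$a))
}

#' @rdname tidy.cf_lda
#' @method glance cf_lda
#' @export
glance.cf_lda <- function(x, ...) {
  tibble::tibble(dims = x$dims, priors = x$priors,
                 n_cf = if (is.null(x$n)) NA_integer_ else x$n[["CF"]],
                 n_para = if (is.null(x$n)) NA_integer_ else x$n[["paraCF"]])
}

#' Tidy a session result
#'
#' One row per record per eye with features and decisions.
#'
#' @param x a `session_result`.
#' @param ... unused.
#' @method tidy session_result
#' @export
tidy.session_result <- function(x, ...) {
  x$features
}

#' @rdname tidy.session_result
#' @method glance session_result
#' @export
glance.session_result <- function(x, ...) {
  tibble::tibble(subject = x$subject,
                 cf_left = x$cf_left, cf_right = x$cf_right,
                 fd_left = x$fd_left, fd_right = x$fd_right,
                 alignment_pass = x$alignment_pass)
}
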