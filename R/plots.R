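#' Plot a power spectrum
#'
#' Log-power line plot with the five half-harmonic frequencies marked.
#'
#' @param object an `rbs_spectrum` from [power_spectrum()].
#' @param f_s scan frequency used for the harmonic markers.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot rbs_spectrum
#' @export
autoplot.rbs_spectrum <- function(object, f_s = 30, ...) {
  marks <- tibble::tibble(freq = half_harmonics * f_s,
                          harmonic = paste0(half_harmonics, " f_s"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(data = marks, ggplot2::aes(xintercept = .data$freq),
                        linetype = "dotted", color = "grey40") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power",
                  title = "Power spectrum with half-harmonic markers")
}

#' Plot a focus curve
#'
#' Goodness of focus against trial-lens power, with the pass threshold and
#' the peak/crossing annotations.
#'
#' @param object a `focus_curve`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot focus_curve
#' @export
autoplot.focus_curve <- function(object, ...) {
  thr <- attr(object, "threshold")
  pk <- attr(object, "peak_lens_D")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$lens_power_D, y = .data$goodness,
                               linetype = .data$mode)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = thr, color = "grey40",
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = pk, color = "grey70",
                        linetype = "dotted") +
    ggplot2::labs(x = "added lens power (D)", y = "(C - A)/(C + A)",
                  title = "Focus curve")
}

#' Plot a threshold calibration trace
#'
#' Total L1 calibration error against the candidate threshold, with the
#' chosen minimizer marked.
#'
#' @param object a `cf_threshold` (with its trace).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cf_threshold
#' @export
autoplot.cf_threshold <- function(object, ...) {
  stopifnot(!is.null(object$trace))
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$theta, y = .data$total)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$theta, color = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = expression(theta), y = "total calibration error",
                  title = "Threshold sweep")
}

#' Scatter the calibration feature space
#'
#' Central- against para-central normalized power, colored by label --
#' the plane in which both published decision rules operate.
#'
#' @param features normalized feature tibble with a `label` column.
#' @return a ggplot.
#' @export
plot_features <- function(features) {
  stopifnot(all(c("r_para", "r_cf", "label") %in% names(features)))
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data$r_para, y = .data$r_cf,
                               color = .data$label, shape = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "(P3.5 + P5.5)/P4.5", y = "(P2.5 + P6.5)/P4.5",
                  title = "Calibration feature space")
}
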