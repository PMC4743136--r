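#' One-sided discrete power spectrum
#'
#' Power spectrum of a uniformly sampled signal with the one-sided
#' convention `P(0) = |X_0|^2 / N^2`, `P(f_k) = 2 |X_k|^2 / N^2` for
#' `0 < f_k < f_Nyquist`, under which the bin powers sum to the mean square
#' of the signal (Parseval). No window is applied: the synchronized
#' sampling scheme places every frequency of interest on an exact bin, so
#' the DFT is leakage-free there.
#'
#' @param x numeric vector of samples (at least one full second is assumed
#'   by downstream feature extraction, not enforced here).
#' @param rate sampling rate in Hz.
#' @return a tibble of class `rbs_spectrum` with columns `freq` (Hz) and
#'   `power`.
#' @export
power_spectrum <- function(x, rate) {
  stopifnot(is.numeric(x), length(x) > 0, rate > 0)
  n <- length(x)
  X <- stats::fft(x)
  nyq <- floor(n / 2)
  p <- Mod(X[1:(nyq + 1)])^2 / n^2
  if (nyq >= 2) {
    top <- if (n %% 2 == 0) nyq else nyq + 1   # double all but DC (and Nyquist when even)
    p[2:top] <- 2 * p[2:top]
  }
  out <- tibble::tibble(freq = (0:nyq) * rate / n, power = p)
  class(out) <- c("rbs_spectrum", class(out))
  out
}

half_harmonics <- c(2.5, 3.5, 4.5, 5.5, 6.5)

## fast path: one-sided bin powers at exact frequencies without building
## the full spectrum tibble (used by the per-record feature extractors)
bin_powers_fast <- function(x, rate, freqs, band = 0) {
  n <- length(x)
  bins <- freqs * n / rate
  if (any(abs(bins - round(bins)) > 1e-9)) {
    stop("configuration error: frequency is not aligned with a spectral bin",
         call. = FALSE)
  }
  X <- stats::fft(x)
  purrr::map_dbl(round(bins), function(b) {
    idx <- max(0, b - band):min(floor(n / 2), b + band)
    sum(ifelse(idx == 0 | (n %% 2 == 0 & idx == n / 2), 1, 2) *
          Mod(X[idx + 1])^2 / n^2)
  })
}

bin_power <- function(spec, f, band = 0) {
  df <- spec$freq[2] - spec$freq[1]
  i <- round(f / df) + 1
  if (abs(f - spec$freq[i]) > 1e-6) {
    stop("configuration error: frequency ", f,
         " Hz is not aligned with a spectral bin", call. = FALSE)
  }
  idx <- max(1, i - band):min(nrow(spec), i + band)
  sum(spec$power[idx])
}

#' Extract half-harmonic powers from a record
#'
#' Computes the per-eye power spectrum and reads the five half-harmonic
#' powers `P2.5 ... P6.5` (at 2.5--6.5 times the scan frequency: 75, 105,
#' 135, 165, 195 Hz at the defaults, all exact integer-Hz bins of a
#' one-second record). Typically applied after [phss()]. The feature
#' channel per eye is the sum of the center and annulus detectors
#' (total collected light, robust to defocus) or the center alone.
#'
#' @param p a `raw_record` or `phss_record`.
#' @param cfg scan configuration; defaults to the record's own.
#' @param channel `"sum"` or `"center"`.
#' @param band half-width in bins summed around each harmonic (0 = the
#'   exact bin; synchronized sampling needs no more).
#' @return a tibble with one row per eye: `subject`, `record`, `eye`,
#'   `P2_5`, `P3_5`, `P4_5`, `P5_5`, `P6_5`.
#' @export
extract_features <- function(p, cfg = NULL, channel = c("sum", "center"),
                             band = 0) {
  stopifnot(inherits(p, "raw_record"))
  channel <- match.arg(channel)
  cfg <- cfg %||% p$cfg
  rate <- cfg$pacing_rate
  freqs <- half_harmonics * cfg$f_s
  if (any(abs(freqs * ncol(p$samples) / rate -
              round(freqs * ncol(p$samples) / rate)) > 1e-9)) {
    stop("configuration error: half-harmonic frequencies are not bin-aligned",
         call. = FALSE)
  }
  pw <- purrr::map(c(1, 2), function(e) {
    x <- if (channel == "sum")
      p$samples[2 * e - 1, ] + p$samples[2 * e, ]
    else p$samples[2 * e - 1, ]
    bin_powers_fast(x, rate, freqs, band = band)
  })
  m <- do.call(rbind, pw)
  tibble::tibble(subject = p$meta$subject %||% NA_character_,
                 record = p$meta$record %||% NA_integer_,
                 eye = c("left", "right"),
                 P2_5 = m[, 1], P3_5 = m[, 2], P4_5 = m[, 3],
                 P5_5 = m[, 4], P6_5 = m[, 5])
}

#' Normalize half-harmonic powers by the carrier
#'
#' The five powers depend on subject-specific factors (pupil size, fundus
#' reflectivity, corneal birefringence, channel gain); dividing by the
#' gaze-independent carrier power `P4.5` leaves ratios that depend mainly
#' on the direction of gaze. Adds the columns
#' `r_cf = (P2_5 + P6_5)/P4_5`, `r_para = (P3_5 + P5_5)/P4_5`,
#' `r25`, `r35`, `r55`, `r65` (each power over `P4_5`) and `usable`.
#'
#' A record whose carrier power is below `floor` times its total
#' half-harmonic power is degenerate (e.g. a blink): with
#' `on_degenerate = "error"` this is an error; with `"flag"` the row is
#' marked `usable = FALSE` with `NA` ratios and is excluded from
#' classification but still counted in the session denominator.
#'
#' @param f tibble with columns `P2_5 ... P6_5` (from
#'   [extract_features()]).
#' @param on_degenerate `"error"` or `"flag"`.
#' @param floor relative carrier-power floor.
#' @return the input tibble with ratio columns and `usable` appended.
#' @export
normalize_features <- function(f, on_degenerate = c("error", "flag"),
                               floor = 1e-12) {
  on_degenerate <- match.arg(on_degenerate)
  need <- c("P2_5", "P3_5", "P4_5", "P5_5", "P6_5")
  stopifnot(all(need %in% names(f)))
  total <- f$P2_5 + f$P3_5 + f$P4_5 + f$P5_5 + f$P6_5
  bad <- !(f$P4_5 > floor * total) | !is.finite(f$P4_5)
  if (any(bad) && on_degenerate == "error") {
    stop("degenerate record: carrier power P4.5 is zero or below the floor",
         call. = FALSE)
  }
  p45 <- ifelse(bad, NA_real_, f$P4_5)
  dplyr::mutate(tibble::as_tibble(f),
                r_cf = (.data$P2_5 + .data$P6_5) / p45,
                r_para = (.data$P3_5 + .data$P5_5) / p45,
                r25 = .data$P2_5 / p45, r35 = .data$P3_5 / p45,
                r55 = .data$P5_5 / p45, r65 = .data$P6_5 / p45,
                usable = !bad)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
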