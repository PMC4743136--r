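#' Normalized goodness of focus
#'
#' `(C - A) / (C + A)`, where `C` and `A` are the carrier-frequency
#' (4.5 x f_s) signal magnitudes on the center and annulus detectors of
#' the bull's-eye photodetector. 1 means all returning light concentrated
#' on the center (perfect focus); 0 means an even split; the screening
#' pass threshold is 0.65. Scale-invariant: multiplying both detectors by
#' a common factor leaves it unchanged.
#'
#' @param C,A non-negative center/annulus magnitudes (vectorized).
#' @return numeric in `[-1, 1]`.
#' @export
focus_goodness <- function(C, A) {
  stopifnot(all(C >= 0, na.rm = TRUE), all(A >= 0, na.rm = TRUE))
  if (any(C + A == 0, na.rm = TRUE)) {
    stop("degenerate record: center + annulus signal is zero", call. = FALSE)
  }
  (C - A) / (C + A)
}

#' Extract per-eye focus features from a record
#'
#' Reads the carrier-bin (4.5 x f_s) spectral power of the center and
#' annulus channels separately (typically after [phss()]) and reports
#' their square roots as the signal magnitudes `C` and `A`, together with
#' the goodness of focus. Using magnitudes makes the statistic linear in
#' the optical center/annulus energy split: a blur that sends fraction
#' `f` of the light to the annulus gives goodness `1 - 2 f` exactly.
#'
#' @param p a `raw_record` or `phss_record`.
#' @param cfg scan configuration; defaults to the record's own.
#' @return tibble with one row per eye: `subject`, `record`, `eye`, `C`,
#'   `A`, `goodness`.
#' @export
extract_focus_features <- function(p, cfg = NULL) {
  stopifnot(inherits(p, "raw_record"))
  cfg <- cfg %||% p$cfg
  rate <- cfg$pacing_rate
  f45 <- 4.5 * cfg$f_s
  ca <- purrr::map(c(1, 2), function(e) {
    C <- sqrt(bin_powers_fast(p$samples[2 * e - 1, ], rate, f45))
    A <- sqrt(bin_powers_fast(p$samples[2 * e, ], rate, f45))
    c(C, A)
  })
  m <- do.call(rbind, ca)
  tibble::tibble(subject = p$meta$subject %||% NA_character_,
                 record = p$meta$record %||% NA_integer_,
                 eye = c("left", "right"), C = m[, 1], A = m[, 2],
                 goodness = ifelse(m[, 1] + m[, 2] > 0,
                                   (m[, 1] - m[, 2]) / (m[, 1] + m[, 2]),
                                   NA_real_))
}

#' Session-level focus decision
#'
#' A record passes when its goodness of focus is at least `threshold`
#' (the boundary value itself passes: the published threshold is the limit
#' of acceptable focus, in contrast to the strict inequality of the
#' central-fixation criterion); the eye passes the session when at least
#' `k` of the `n` records pass.
#'
#' @param goodness_values numeric vector of per-record goodness values.
#' @param threshold pass threshold.
#' @param k required passing records.
#' @param n expected number of records.
#' @return single logical.
#' @export
focus_decision <- function(goodness_values, threshold = 0.65, k = 2, n = 12) {
  if (length(goodness_values) != n) {
    stop("expected exactly ", n, " goodness values", call. = FALSE)
  }
  sum(goodness_values >= threshold, na.rm = TRUE) >= k
}

#' Monocular focus curve over a trial-lens series
#'
#' For each trial lens power the accommodative state is evaluated
#' ([effective_defocus()]), the resulting center/annulus split is applied
#' ([defocus_split()]), a record is synthesized and the goodness of focus
#' extracted -- emulating the clinical focus-curve procedure with
#' ophthalmic trial lenses in 0.25 D steps. Cycloplegia paralyzes
#' accommodation and (with the accompanying dilation) steepens the curve:
#' `dilation_factor` scales the blur scale down when the state is
#' cyclopleged.
#'
#' The returned object records the lens power of peak goodness and the
#' lens power at which the curve falls to `threshold` on the plus side of
#' the peak (linear interpolation between grid points).
#'
#' @param f a [focus_state()] template (its `lens_power_D` is replaced).
#' @param lens_powers_D numeric vector of trial lens powers (>= 2 values).
#' @param eye an [eye_optics()].
#' @param cfg a [scan_config()].
#' @param noise a [noise_spec()]; default noise-free for clean curves.
#' @param blur_scale_D blur scale of the undilated eye.
#' @param dilation_factor blur-scale multiplier under cycloplegic
#'   dilation.
#' @param threshold pass threshold for the crossing annotation.
#' @param seed RNG seed for the synthesized records.
#' @return a tibble of class `focus_curve` with columns `lens_power_D`,
#'   `defocus_D`, `goodness`, `mode`, and attributes `peak_lens_D`,
#'   `crossing_lens_D`.
#' @export
focus_curve <- function(f, lens_powers_D, eye = eye_optics(),
                        cfg = scan_config(),
                        noise = noise_spec(background_amp = 0, line_amp = 0,
                                           white_sigma = 0),
                        blur_scale_D = 2.28, dilation_factor = 0.5,
                        threshold = 0.65, seed = 1L) {
  stopifnot(inherits(f, "focus_state"), length(lens_powers_D) >= 2)
  scale <- if (f$cyclopleged) blur_scale_D * dilation_factor else blur_scale_D
  rows <- purrr::map(seq_along(lens_powers_D), function(i) {
    fi <- f
    fi$lens_power_D <- lens_powers_D[i]
    d <- effective_defocus(fi)
    rec <- synthesize_record(list(eye, eye), list(fi, fi), noise, cfg,
                             seed = seed + i, blur_scale_D = scale)
    ff <- extract_focus_features(phss(rec))
    tibble::tibble(lens_power_D = lens_powers_D[i], defocus_D = d,
                   goodness = ff$goodness[ff$eye == "left"])
  })
  out <- dplyr::bind_rows(rows)
  out$mode <- if (f$cyclopleged) "cyclopleged" else "natural"
  ## under active accommodation the curve has a best-focus plateau on the
  ## minus-lens side; the peak is its plus-side end (best focus with the
  ## least accommodative effort)
  top <- which(out$goodness >= max(out$goodness) - 1e-9)
  peak_i <- top[length(top)]
  crossing <- NA_real_
  g <- out$goodness; lp <- out$lens_power_D
  for (i in seq(peak_i, length(g) - 1)) {
    if (g[i] >= threshold && g[i + 1] < threshold) {
      crossing <- lp[i] + (g[i] - threshold) / (g[i] - g[i + 1]) * (lp[i + 1] - lp[i])
      break
    }
  }
  structure(tibble::as_tibble(out),
            peak_lens_D = lp[peak_i], crossing_lens_D = crossing,
            threshold = threshold,
            class = c("focus_curve", class(out)))
}

#' Shift a viewing distance by a dioptric offset
#'
#' Converts a distance to vergence (`100 / distance_cm` diopters),
#' subtracts `delta_D`, and converts back. Used for target conjugacy: an
#' image placed 0.75 D farther away than a 33.3 cm target sits at 44.4 cm.
#'
#' @param distance_cm viewing distance in centimeters (> 0).
#' @param delta_D dioptric offset to subtract.
#' @return distance in centimeters.
#' @export
dioptric_conjugate <- function(distance_cm, delta_D) {
  stopifnot(all(distance_cm > 0))
  v <- 100 / distance_cm - delta_D
  if (any(v <= 0)) {
    stop("resulting vergence is not positive: conjugate beyond infinity",
         call. = FALSE)
  }
  100 / v
}
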