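## Synthetic four-channel record generation: physics signal + defocus
## split + scan-synchronous background + line interference + white noise.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Effective defocus of the retinal conjugate
#'
#' Dioptric distance between the eye's focus and the target, given the
#' accommodative state. The accommodative demand is
#' `stimulus_vergence + refraction - lens_power`; the response is zero
#' under cycloplegia, and otherwise that of a perfect accommodator pinned
#' at its tonic level: `clamp(demand, tonic, tonic + amplitude)` (tonic
#' accommodation cannot be relaxed, and response saturates at the
#' accommodative amplitude). The returned defocus is `demand - response`.
#'
#' Worked arithmetic: a cyclopleged eye with +1.00 D refraction viewing a
#' 3.00 D target through a +4.00 D lens has demand 0 and defocus 0 (best
#' focus); without cycloplegia and with +0.75 D of tonic accommodation the
#' same eye reaches best focus with only +3.25 D of lens power
#' (0.75 + 3.25 = 4.00 D).
#'
#' @param f a [focus_state()].
#' @return effective defocus in diopters (0 = best focus; negative =
#'   focused in front of the target).
#' @export
effective_defocus <- function(f) {
  stopifnot(inherits(f, "focus_state"))
  demand <- f$stimulus_vergence_D + f$refraction_D - f$lens_power_D
  response <- if (f$cyclopleged) 0 else
    min(max(demand, f$tonic_D), f$tonic_D + f$accommodation_amplitude_D)
  demand - response
}

#' Fraction of returning light spilling onto the annulus
#'
#' With poor focus part of the double-pass return misses the center of the
#' bull's-eye photodetector and lands on the annulus. The split is modeled
#' as `f_A(d) = 1 - exp(-(d / blur_scale)^2)`: smooth, even in the defocus
#' `d`, zero at best focus and saturating toward 1 -- the qualitative shape
#' of measured focus curves. The default `blur_scale_D = 2.28` places the
#' 0.65 goodness-of-focus crossing at 1.00 D of defocus exactly
#' (`1 - 2 * f_A(1) = 0.65`, i.e. `f_A = 0.175`); a dilated pupil is
#' emulated by scaling `blur_scale_D` down (more blur per diopter).
#'
#' @param d defocus in diopters (vectorized).
#' @param blur_scale_D blur scale in diopters, > 0.
#' @return annulus fraction(s) in `[0, 1)`.
#' @export
defocus_split <- function(d, blur_scale_D = 2.28) {
  stopifnot(blur_scale_D > 0)
  1 - exp(-(d / blur_scale_D)^2)
}

scan_angles <- function(cfg) {
  (0:(cfg$samples_per_record - 1)) * 360 / cfg$steps_per_rev
}

## one revolution of exactly steps_per_rev-periodic background, tiled
draw_background <- function(cfg, noise) {
  spr <- cfg$steps_per_rev
  k <- 0:(spr - 1)
  base <- numeric(spr)
  for (m in seq_len(noise$background_harmonics)) {
    a <- stats::rnorm(1, 0, noise$background_amp / m)
    b <- stats::rnorm(1, 0, noise$background_amp / m)
    base <- base + a * cos(2 * pi * m * k / spr) + b * sin(2 * pi * m * k / spr)
  }
  rep(base, cfg$samples_per_record / spr)
}

draw_channel_noise <- function(cfg, noise) {
  n <- cfg$samples_per_record
  t <- (0:(n - 1)) / cfg$pacing_rate
  bg <- draw_background(cfg, noise)
  line <- noise$line_amp * sin(2 * pi * cfg$line_freq * t + stats::runif(1, 0, 2 * pi))
  white <- stats::rnorm(n, 0, noise$white_sigma)
  bg + line + white
}

## per-harmonic gain applied in the frequency domain (the analog
## programmable-gain stage; harmonics in units of f_s)
apply_harmonic_gains <- function(x, gains, cfg) {
  if (is.null(gains) || !length(gains)) return(x)
  n <- length(x)
  X <- stats::fft(x)
  for (h in names(gains)) {
    f <- as.numeric(h) * cfg$f_s
    bin <- round(f * cfg$record_seconds * n / (cfg$pacing_rate * cfg$record_seconds))
    if (bin < 1 || bin > n / 2) next
    X[bin + 1] <- X[bin + 1] * gains[[h]]
    X[n + 1 - bin] <- X[n + 1 - bin] * gains[[h]]
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Default per-harmonic channel gains
#'
#' Relative gains of the analog acquisition channel at the half-harmonic
#' frequencies, in units of the scan frequency. The strong spin-generated
#' carrier at `4.5 x f_s` is acquired with substantially less gain than the
#' fixation sidebands so that it does not saturate the channel; all other
#' frequencies are passed at unit gain. The default carrier gain of 0.07
#' places the normalized central-fixation ratios of the synthetic
#' calibration population around the instrument's operating threshold.
#'
#' @param carrier_gain relative gain at `4.5 x f_s`.
#' @return named numeric vector mapping harmonic index to gain.
#' @export
default_harmonic_gains <- function(carrier_gain = 0.07) {
  c("4.5" = carrier_gain)
}

#' Synthesize one four-channel one-second record
#'
#' Composes the Mueller-matrix polarization signal for each eye, splits it
#' between the center and annulus detectors according to the eye's
#' effective defocus, applies the per-harmonic channel gains, and adds
#' scan-synchronous background, power-line interference and white noise
#' (independent draws per channel). Channel order is left-center,
#' left-annulus, right-center, right-annulus.
#'
#' @param eyes list of two [eye_optics()] objects, `left` and `right` (a
#'   single object is used for both).
#' @param focus list of two [focus_state()] objects, or a single one.
#' @param noise a [noise_spec()].
#' @param cfg a [scan_config()].
#' @param seed integer seed; identical seeds give identical records.
#' @param subject,record identifiers carried in the record metadata.
#' @param blur_scale_D blur scale passed to [defocus_split()].
#' @param harmonic_gains named gain vector, see [default_harmonic_gains()].
#' @return an object of class `raw_record`: list with `samples` (4 x N
#'   matrix, rows `LC`, `LA`, `RC`, `RA`), `cfg` and `meta`.
#' @export
synthesize_record <- function(eyes, focus = focus_state(), noise = noise_spec(),
                              cfg = scan_config(), seed = NULL,
                              subject = NA_character_, record = NA_integer_,
                              blur_scale_D = 2.28,
                              harmonic_gains = default_harmonic_gains()) {
  if (inherits(eyes, "eye_optics")) eyes <- list(left = eyes, right = eyes)
  if (inherits(focus, "focus_state")) focus <- list(left = focus, right = focus)
  stopifnot(length(eyes) == 2L, length(focus) == 2L,
            inherits(noise, "noise_spec"), inherits(cfg, "scan_config"))

  phi <- scan_angles(cfg)
  n <- cfg$samples_per_record

  ## At the design ratio 9/16 the detected signal repeats exactly every two
  ## scan revolutions (all surviving spectral lines are integer multiples of
  ## f_s/2), so one base period can be tiled across the record.
  base_len <- 2L * cfg$steps_per_rev
  tile <- isTRUE(all.equal(cfg$hwp_ratio, 9 / 16)) && n %% base_len == 0
  eye_signal <- function(eye) {
    if (tile) {
      rep(detector_sample(phi[seq_len(base_len)], eye, cfg), n / base_len)
    } else {
      detector_sample(phi, eye, cfg)
    }
  }

  build <- function() {
    samples <- matrix(0, 4, n, dimnames = list(c("LC", "LA", "RC", "RA"), NULL))
    defocus <- numeric(2)
    for (e in 1:2) {
      sig <- eye_signal(eyes[[e]])
      d <- effective_defocus(focus[[e]])
      defocus[e] <- d
      fA <- defocus_split(d, blur_scale_D)
      centr <- (1 - fA) * sig + draw_channel_noise(cfg, noise)
      annul <- fA * sig + draw_channel_noise(cfg, noise)
      samples[2 * e - 1, ] <- apply_harmonic_gains(centr, harmonic_gains, cfg)
      samples[2 * e, ] <- apply_harmonic_gains(annul, harmonic_gains, cfg)
    }
    list(samples = samples, defocus = defocus)
  }
  out <- with_seed(seed, build())

  structure(list(
    samples = out$samples, cfg = cfg,
    meta = list(subject = subject, record = record, seed = seed,
                offset_left = eyes[[1]]$fixation_offset_deg,
                offset_right = eyes[[2]]$fixation_offset_deg,
                defocus_left = out$defocus[1], defocus_right = out$defocus[2])),
    class = "raw_record")
}

#' @export
print.raw_record <- function(x, ...) {
  cat("<raw_record> 4 x ", ncol(x$samples), " samples, subject ",
      x$meta$subject, ", record ", x$meta$record, "\n", sep = "")
  invisible(x)
}

#' Generate a labeled calibration feature set
#'
#' Emulates the calibration protocol: for each subject, per-eye corneal
#' parameters are drawn at random (retardance uniform on 20--80 degrees,
#' axis uniform on 0--180), then `records_per_condition` one-second records
#' are acquired with central fixation and with the gaze directed at four
#' imaginary targets on the scan circle (1.5 degrees off center, at 12, 3,
#' 6 and 9 o'clock). Every record is processed through phase-shift
#' subtraction and spectral feature extraction, yielding one labeled
#' normalized-feature row per eye per record: `n_subjects * 12 * 2` rows
#' labeled `CF` and four times as many labeled `paraCF` (120 and 480 at the
#' defaults).
#'
#' @param n_subjects number of simulated subjects.
#' @param cfg a [scan_config()].
#' @param noise a [noise_spec()].
#' @param seed integer seed for the whole set.
#' @param records_per_condition records per gaze condition.
#' @return a tibble with subject, eye, record, condition, label, the five
#'   half-harmonic powers and their normalized ratios.
#' @export
make_calibration_set <- function(n_subjects = 5, cfg = scan_config(),
                                 noise = noise_spec(), seed = 1L,
                                 records_per_condition = 12) {
  stopifnot(n_subjects >= 1)
  r <- cfg$scan_radius_deg
  offsets <- list(CF = c(0, 0),
                  "paraCF-12" = c(0, r), "paraCF-3" = c(r, 0),
                  "paraCF-6" = c(0, -r), "paraCF-9" = c(-r, 0))
  rows <- with_seed(seed, {
    purrr::map(seq_len(n_subjects), function(s) {
      eyes0 <- purrr::map(1:2, function(e)
        eye_optics(corneal_retardance_deg = stats::runif(1, 20, 80),
                   corneal_axis_deg = stats::runif(1, 0, 180)))
      purrr::imap(offsets, function(off, cond) {
        eyes <- purrr::map(eyes0, function(ey) {
          ey$fixation_offset_deg <- off
          ey
        })
        purrr::map(seq_len(records_per_condition), function(k) {
          rec <- synthesize_record(eyes, focus_state(stimulus_vergence_D = 0),
                                   noise, cfg,
                                   seed = sample.int(.Machine$integer.max, 1),
                                   subject = paste0("S", s), record = k)
          feats <- extract_features(phss(rec), channel = "sum")
          feats$condition <- cond
          feats$label <- if (identical(cond, "CF")) "CF" else "paraCF"
          feats
        })
      })
    })
  })
  out <- dplyr::bind_rows(purrr::list_flatten(purrr::list_flatten(rows)))
  normalize_features(out, on_degenerate = "flag")
}
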