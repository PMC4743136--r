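#' Scan and sampling configuration
#'
#' Ties all processing stages together: the step motor is paced at
#' `pacing_rate` steps per second with `steps_per_rev` steps per scan
#' revolution, so the scan frequency is `f_s = pacing_rate / steps_per_rev`
#' (30 rotations/s at the defaults). One sample per channel is acquired at
#' every step, so sample `k` of a record corresponds to scan angle
#' `k * 360 / steps_per_rev` degrees. The defaults lock the sampling chain
#' to the 60 Hz power line (6000 = 100 x 60), which places exactly two line
#' cycles in every scan revolution, and every half-harmonic of interest on
#' an exact integer-Hz DFT bin of a one-second record.
#'
#' @param pacing_rate sampling/stepping rate, steps per second.
#' @param steps_per_rev motor steps (= samples) per scan revolution.
#' @param hwp_ratio half-wave-plate spin rate as a fraction of the scan
#'   rate (9/16 generates the half-harmonic signal family).
#' @param scan_radius_deg visual-angle radius of the scan circle (1.5
#'   degrees: a 3 degree diameter circle).
#' @param line_freq power-line frequency, Hz.
#' @param record_seconds record duration, seconds; must give an integer
#'   number of scan revolutions per record.
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(pacing_rate = 6000, steps_per_rev = 200,
                        hwp_ratio = 9 / 16, scan_radius_deg = 1.5,
                        line_freq = 60, record_seconds = 1) {
  stopifnot(pacing_rate > 0, steps_per_rev > 0,
            steps_per_rev == round(steps_per_rev),
            scan_radius_deg > 0, line_freq > 0, record_seconds > 0)
  f_s <- pacing_rate / steps_per_rev
  n <- pacing_rate * record_seconds
  if (abs(n - round(n)) > 1e-9) {
    stop("configuration error: non-integer number of samples per record",
         call. = FALSE)
  }
  n <- round(n)
  if (n %% steps_per_rev != 0) {
    stop("configuration error: record must span an integer number of scan revolutions",
         call. = FALSE)
  }
  structure(list(pacing_rate = pacing_rate, steps_per_rev = steps_per_rev,
                 f_s = f_s, hwp_ratio = hwp_ratio,
                 scan_radius_deg = scan_radius_deg, line_freq = line_freq,
                 record_seconds = record_seconds, samples_per_record = n),
            class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat("<scan_config> ", x$pacing_rate, " S/s, ", x$steps_per_rev,
      " steps/rev, f_s = ", x$f_s, " rps, HWP ratio ", format(x$hwp_ratio),
      ", radius ", x$scan_radius_deg, " deg, ", x$record_seconds, " s\n",
      sep = "")
  invisible(x)
}

#' Ocular polarization parameters of one eye
#'
#' The corneal retarder is a fixed linear retarder; the Henle fiber layer
#' is a weak retarder whose axis is radial about the foveal center (slow
#' axis radial by default). `fixation_offset_deg` is the position of the
#' foveal center relative to the scan center in degrees of visual angle:
#' `c(0, 0)` is central fixation, a vector of magnitude 1.5 places the
#' fovea on the scan circle (the para-central calibration condition).
#'
#' @param corneal_retardance_deg corneal retardance, degrees (single pass).
#' @param corneal_axis_deg corneal fast-axis azimuth, degrees.
#' @param henle_retardance_deg Henle-layer retardance at the scan radius,
#'   degrees (single pass).
#' @param fundus_reflectance fraction of incident light returned by the
#'   fundus, in `[0, 1]`.
#' @param depolarized_fraction fraction of the returned light that is
#'   depolarized (skin/sclera background source), in `[0, 1]`.
#' @param fixation_offset_deg length-2 numeric, degrees of visual angle.
#' @param henle_slow_axis_radial logical; if `TRUE` (default) the slow axis
#'   is radial (fast axis tangential). Either choice preserves the
#'   harmonic signatures.
#' @param fixed_wp optional fixed wave plate in the train, given as
#'   `c(retardance_deg, axis_deg)`; `NULL` (default) disables the slot.
#' @param foveal_core_deg radius of the fiber-free foveal core within which
#'   Henle retardance tapers linearly to zero.
#' @return an object of class `eye_optics`.
#' @export
eye_optics <- function(corneal_retardance_deg = 45, corneal_axis_deg = 20,
                       henle_retardance_deg = 3, fundus_reflectance = 0.05,
                       depolarized_fraction = 0.3,
                       fixation_offset_deg = c(0, 0),
                       henle_slow_axis_radial = TRUE,
                       fixed_wp = NULL, foveal_core_deg = 0.25) {
  stopifnot(fundus_reflectance >= 0, fundus_reflectance <= 1,
            depolarized_fraction >= 0, depolarized_fraction <= 1,
            length(fixation_offset_deg) == 2L, foveal_core_deg >= 0)
  if (!is.null(fixed_wp)) stopifnot(length(fixed_wp) == 2L)
  structure(list(corneal_retardance_deg = corneal_retardance_deg,
                 corneal_axis_deg = corneal_axis_deg %% 180,
                 henle_retardance_deg = henle_retardance_deg,
                 fundus_reflectance = fundus_reflectance,
                 depolarized_fraction = depolarized_fraction,
                 fixation_offset_deg = as.numeric(fixation_offset_deg),
                 henle_slow_axis_radial = isTRUE(henle_slow_axis_radial),
                 fixed_wp = fixed_wp, foveal_core_deg = foveal_core_deg),
            class = "eye_optics")
}

#' Noise model for synthetic records
#'
#' Three additive components on top of the polarization signal:
#' a scan-synchronous background (exactly `steps_per_rev`-periodic by
#' construction, drawn once per record as a random trigonometric polynomial
#' of `background_harmonics` scan harmonics), power-line interference at
#' `line_freq`, and white Gaussian noise. The background and the line
#' component both repeat over one scan revolution under the synchronized
#' sampling scheme, so phase-shift subtraction removes them exactly; the
#' white component sets the effective spectral noise floor.
#'
#' Default amplitudes are expressed in the same arbitrary intensity units
#' as the polarization signal (whose spin-generated carrier has amplitude
#' of order 1e-2 at the default eye parameters): the background is set an
#' order of magnitude above the signal, as is typical for scleral scatter,
#' and the white noise floor about 20 dB below the fixation sidebands in
#' per-bin power.
#'
#' @param background_amp peak scale of the scan-synchronous background.
#' @param background_harmonics number of scan harmonics in the background.
#' @param line_amp amplitude of the power-line component.
#' @param white_sigma standard deviation of the white noise.
#' @param seed optional integer; per-record draws are derived from it.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(background_amp = 0.02, background_harmonics = 8,
                       line_amp = 0.01, white_sigma = 5e-4, seed = NULL) {
  stopifnot(background_amp >= 0, line_amp >= 0, white_sigma >= 0,
            background_harmonics >= 1)
  structure(list(background_amp = background_amp,
                 background_harmonics = as.integer(background_harmonics),
                 line_amp = line_amp, white_sigma = white_sigma, seed = seed),
            class = "noise_spec")
}

#' Accommodative state of one eye during a measurement
#'
#' All quantities are in diopters. `stimulus_vergence_D` is the vergence of
#' the fixation target (3.0 D for the standard 33.3 cm testing distance);
#' `refraction_D` is the eye's (cycloplegic) refractive error referred to
#' infinity, positive for hyperopia; `lens_power_D` is trial lens power
#' added in front of the eye. `tonic_D` is habitual tonic accommodation
#' that the eye cannot relax; `cyclopleged = TRUE` paralyzes accommodation
#' entirely.
#'
#' @param stimulus_vergence_D target vergence, D.
#' @param lens_power_D added trial lens power, D.
#' @param refraction_D refractive error at infinity, D.
#' @param tonic_D tonic accommodation, D (>= 0).
#' @param cyclopleged logical; accommodation paralyzed.
#' @param accommodation_amplitude_D maximum accommodative response beyond
#'   the tonic level, D.
#' @return an object of class `focus_state`.
#' @export
focus_state <- function(stimulus_vergence_D = 3, lens_power_D = 0,
                        refraction_D = 0, tonic_D = 0, cyclopleged = FALSE,
                        accommodation_amplitude_D = 8) {
  stopifnot(tonic_D >= 0, accommodation_amplitude_D >= 0)
  structure(list(stimulus_vergence_D = stimulus_vergence_D,
                 lens_power_D = lens_power_D, refraction_D = refraction_D,
                 tonic_D = tonic_D, cyclopleged = isTRUE(cyclopleged),
                 accommodation_amplitude_D = accommodation_amplitude_D),
            class = "focus_state")
}

#' Study-level configuration for screening sessions
#'
#' Bundles the scan configuration, noise model, decision rules and default
#' decision-model coefficients used by [run_session()] and [run_study()].
#' The central-fixation method is either the optimized scalar threshold on
#' `(P2.5 + P6.5)/P4.5` (`"threshold"`, default threshold 0.8750) or a
#' linear discriminant in 2, 3 or 4 normalized-power dimensions
#' (`"lda2"`, `"lda3"`, `"lda4"`, with published default coefficients).
#' An eye passes a session when at least `k_required` of
#' `records_per_session` records satisfy the criterion (2 of 12).
#'
#' @param scan a [scan_config()].
#' @param noise a [noise_spec()].
#' @param records_per_session records acquired per session.
#' @param k_required minimum passing records for a session-level pass.
#' @param cf_method one of `"threshold"`, `"lda2"`, `"lda3"`, `"lda4"`.
#' @param cf_theta scalar threshold for the `"threshold"` method.
#' @param lda_coefficients named list of numeric coefficient vectors
#'   `a = (a0, a1, ...)` for the discriminant methods.
#' @param fd_threshold goodness-of-focus pass threshold.
#' @param channel central-fixation feature channel: `"sum"` (center +
#'   annulus, defocus robust) or `"center"`.
#' @param seed base RNG seed for simulated sessions.
#' @return an object of class `study_config`.
#' @export
study_config <- function(scan = scan_config(), noise = noise_spec(),
                         records_per_session = 12, k_required = 2,
                         cf_method = c("threshold", "lda2", "lda3", "lda4"),
                         cf_theta = 0.8750,
                         lda_coefficients = list(
                           lda2 = c(0.743, 0.318),
                           lda3 = c(0.768, 0.056, -0.289),
                           lda4 = c(0.779, 0.016, -0.283, 0.083)),
                         fd_threshold = 0.65,
                         channel = c("sum", "center"), seed = 1L) {
  cf_method <- match.arg(cf_method)
  channel <- match.arg(channel)
  stopifnot(k_required >= 1, k_required <= records_per_session)
  structure(list(scan = scan, noise = noise,
                 records_per_session = as.integer(records_per_session),
                 k_required = as.integer(k_required), cf_method = cf_method,
                 cf_theta = cf_theta, lda_coefficients = lda_coefficients,
                 fd_threshold = fd_threshold, channel = channel,
                 seed = as.integer(seed)),
            class = "study_config")
}
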