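#' Mueller rotation matrix
#'
#' Frame-rotation Mueller matrix for a counter-clockwise rotation of the
#' polarization reference frame by `angle_deg` (degrees, viewed against the
#' direction of propagation). Acts on the (s1, s2) plane of a Stokes vector
#' at twice the physical angle, so a 180 degree rotation is the identity.
#'
#' @param angle_deg rotation angle in degrees.
#' @return a 4x4 numeric matrix.
#' @export
#' @examples
#' mueller_rotator(0)           # identity
#' mueller_rotator(17) %*% mueller_rotator(25)  # equals mueller_rotator(42)
mueller_rotator <- function(angle_deg) {
  stopifnot(is.numeric(angle_deg), length(angle_deg) == 1L, is.finite(angle_deg))
  t <- 2 * angle_deg * pi / 180
  c2 <- cos(t); s2 <- sin(t)
  matrix(c(1, 0, 0, 0,
           0, c2, s2, 0,
           0, -s2, c2, 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

#' Linear retarder Mueller matrix
#'
#' Mueller matrix of a homogeneous linear retarder with phase retardance
#' `retardance_deg` and fast axis at azimuth `axis_deg` (counter-clockwise
#' from horizontal, viewed against propagation). Implemented as
#' `R(-axis) C(delta) R(axis)` where `C` is the canonical retarder with
#' horizontal fast axis. A zero-retardance element is the identity; a
#' half-wave plate (180 degrees) at axis theta maps linear polarization at
#' azimuth alpha to azimuth `2*theta - alpha`.
#'
#' The handedness convention is fixed by the canonical retarder: a
#' quarter-wave plate at 45 degrees maps horizontal linear light
#' `(1, 1, 0, 0)` to right-circular `(1, 0, 0, 1)`.
#'
#' @param retardance_deg phase retardance in degrees (taken modulo 360).
#' @param axis_deg fast-axis azimuth in degrees (taken modulo 180).
#' @return a 4x4 numeric matrix.
#' @export
mueller_retarder <- function(retardance_deg, axis_deg = 0) {
  stopifnot(is.numeric(retardance_deg), length(retardance_deg) == 1L,
            is.finite(retardance_deg),
            is.numeric(axis_deg), length(axis_deg) == 1L, is.finite(axis_deg))
  d <- (retardance_deg %% 360) * pi / 180
  cd <- cos(d); sd <- sin(d)
  canon <- matrix(c(1, 0, 0, 0,
                    0, 1, 0, 0,
                    0, 0, cd, sd,
                    0, 0, -sd, cd), 4, 4, byrow = TRUE)
  mueller_rotator(-axis_deg) %*% canon %*% mueller_rotator(axis_deg)
}

#' Azimuth of the radial Henle-fiber direction at a scanned point
#'
#' The Henle fiber layer is radially symmetric about the foveal center. For
#' a scan circle of radius `radius_deg` whose center is displaced from the
#' fovea by `offset_deg` (a 2-vector of visual angle, fovea position
#' relative to the scan center), the scanned retinal point at scan angle
#' `phi` is `radius * (cos phi, sin phi)` and the fiber orientation there is
#' the azimuth of the vector from the foveal center to that point.
#'
#' With a centered scan the axis equals the scan angle, completing one full
#' axis cycle per revolution -- the origin of the `2 f_s` polarization
#' signature. With the fovea displaced onto the scan circle (the
#' para-central calibration condition) the axis advances at half the scan
#' rate.
#'
#' @param scan_angle_deg scan angle(s) phi in degrees (0 = +x direction).
#' @param offset_deg length-2 numeric, fovea center relative to the scan
#'   center, degrees of visual angle.
#' @param radius_deg scan radius, degrees of visual angle.
#' @return numeric vector of axis azimuths in degrees.
#' @export
henle_axis <- function(scan_angle_deg, offset_deg = c(0, 0), radius_deg = 1.5) {
  stopifnot(is.numeric(scan_angle_deg), length(offset_deg) == 2L,
            radius_deg > 0)
  phi <- scan_angle_deg * pi / 180
  px <- radius_deg * cos(phi) - offset_deg[1]
  py <- radius_deg * sin(phi) - offset_deg[2]
  r <- sqrt(px^2 + py^2)
  if (any(r < 1e-12)) {
    stop("invalid geometry: scanned point coincides with the foveal center",
         call. = FALSE)
  }
  atan2(py, px) * 180 / pi
}

## Vectorized Stokes propagation helpers. States are stored as an N x 4
## matrix; each optical element is applied as a few elementwise operations,
## which keeps a full 6000-sample record cheap.

stokes_rotate <- function(S, angle_deg) {
  t <- 2 * angle_deg * pi / 180
  c2 <- cos(t); s2 <- sin(t)
  s1 <- S[, 2]; s2v <- S[, 3]
  S[, 2] <- c2 * s1 + s2 * s2v
  S[, 3] <- -s2 * s1 + c2 * s2v
  S
}

stokes_canonical_retard <- function(S, retardance_deg) {
  d <- retardance_deg * pi / 180
  cd <- cos(d); sd <- sin(d)
  s2 <- S[, 3]; s3 <- S[, 4]
  S[, 3] <- cd * s2 + sd * s3
  S[, 4] <- -sd * s2 + cd * s3
  S
}

stokes_retard <- function(S, retardance_deg, axis_deg) {
  S <- stokes_rotate(S, axis_deg)
  S <- stokes_canonical_retard(S, retardance_deg)
  stokes_rotate(S, -axis_deg)
}

#' Detected intensity of the double-pass scanning polarimeter
#'
#' Propagates horizontal linearly polarized light through the instrument's
#' retarder train, sample by sample around the scan circle, and returns the
#' intensity of the polarization-changed return -- the component orthogonal
#' to the source polarization, which the polarizing beam splitter routes to
#' the detector. The train is
#' `HWP(psi) -> [fixed WP] -> cornea -> Henle(axis(phi)) -> fundus mirror ->
#' Henle -> cornea -> [fixed WP] -> HWP(psi) -> analyzer`,
#' with the half-wave-plate angle `psi = hwp_ratio * phi + hwp_phase`.
#'
#' On the return pass every element is traversed with its axis mirrored
#' (axis -> -axis), the standard convention for viewing the retracing beam
#' against its propagation direction; the fundus is an ideal specular mirror
#' `diag(1, 1, -1, -1)` scaled by `fundus_reflectance`. Under this
#' convention the gaze-independent spin-generated carrier of the detected
#' signal sits at `4.5 x f_s` when `hwp_ratio = 9/16`, and the spectrum
#' contains only integer and half-integer harmonics of the scan frequency.
#'
#' The depolarized fraction of the return (skin/sclera scatter) splits
#' evenly at the beam splitter and contributes a term independent of the
#' half-wave-plate angle; it is constant over the scan here and cancels in
#' phase-shift subtraction.
#'
#' Henle retardance tapers linearly to zero inside `foveal_core_deg` of the
#' foveal center, where no oriented fibers exist; this keeps the model
#' defined when the scan circle crosses the foveal center (the para-central
#' calibration geometry). With `foveal_core_deg = 0` a scanned point landing
#' exactly on the foveal center is a geometry error.
#'
#' @param scan_angle_deg scan angle(s) in degrees; may be a vector.
#' @param eye an [eye_optics()] object.
#' @param cfg a [scan_config()] object (supplies the scan radius).
#' @param hwp_phase_deg half-wave-plate phase at scan angle zero, degrees.
#' @param components if `TRUE`, return a tibble with the per-sample energy
#'   budget (detected, transmitted, depolarized, reflected) instead of the
#'   detected intensity alone.
#' @return numeric vector of detected intensities, or a tibble when
#'   `components = TRUE`.
#' @export
detector_sample <- function(scan_angle_deg, eye, cfg = scan_config(),
                            hwp_phase_deg = 0, components = FALSE) {
  stopifnot(inherits(eye, "eye_optics"), inherits(cfg, "scan_config"))
  phi <- scan_angle_deg
  n <- length(phi)
  psi <- cfg$hwp_ratio * phi + hwp_phase_deg

  ## radial geometry relative to the foveal center
  r <- cfg$scan_radius_deg
  prad <- phi * pi / 180
  px <- r * cos(prad) - eye$fixation_offset_deg[1]
  py <- r * sin(prad) - eye$fixation_offset_deg[2]
  d <- sqrt(px^2 + py^2)
  core <- eye$foveal_core_deg
  if (core <= 0 && any(d < 1e-12)) {
    stop("invalid geometry: scanned point coincides with the foveal center",
         call. = FALSE)
  }
  hax <- ifelse(d < 1e-12, 0, atan2(py, px) * 180 / pi)
  if (eye$henle_slow_axis_radial) hax <- hax + 90   # fast axis tangential
  taper <- if (core > 0) pmin(d / core, 1) else rep(1, n)
  dh <- eye$henle_retardance_deg * taper

  S <- matrix(rep(c(1, 1, 0, 0), each = n), n, 4)

  apply_elem <- function(S, delta, axis) {
    # delta and/or axis may be per-sample vectors
    S <- stokes_rotate(S, axis)
    S <- stokes_canonical_retard(S, delta)
    stokes_rotate(S, -axis)
  }

  wp <- eye$fixed_wp   # NULL or c(retardance, axis)
  S <- apply_elem(S, 180, psi)                                  # HWP forward
  if (!is.null(wp)) S <- apply_elem(S, wp[1], wp[2])
  S <- apply_elem(S, eye$corneal_retardance_deg, eye$corneal_axis_deg)
  S <- apply_elem(S, dh, hax)                                   # Henle forward
  S[, 3] <- -S[, 3]; S[, 4] <- -S[, 4]                          # fundus mirror
  S <- apply_elem(S, dh, -hax)                                  # Henle return
  S <- apply_elem(S, eye$corneal_retardance_deg, -eye$corneal_axis_deg)
  if (!is.null(wp)) S <- apply_elem(S, wp[1], -wp[2])
  S <- apply_elem(S, 180, -psi)                                 # HWP return

  pol_scale <- eye$fundus_reflectance * (1 - eye$depolarized_fraction)
  depol <- eye$fundus_reflectance * eye$depolarized_fraction
  detected_pol <- pol_scale * (S[, 1] - S[, 2]) / 2
  transmitted <- pol_scale * (S[, 1] + S[, 2]) / 2
  detected <- detected_pol + depol / 2

  if (components) {
    tibble::tibble(
      scan_angle_deg = phi,
      detected = detected,
      detected_polarized = detected_pol,
      transmitted = transmitted,
      depolarized = rep(depol, n),
      reflected = transmitted + detected_pol + depol
    )
  } else {
    detected
  }
}
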