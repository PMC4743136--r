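test_that("rotator matrices form the expected one-parameter group", {
  expect_equal(mueller_rotator(0), diag(4))
  expect_equal(mueller_rotator(180), diag(4))  # period 180 on Stokes space
  expect_equal(mueller_rotator(17) %*% mueller_rotator(25),
               mueller_rotator(42), tolerance = 1e-12)
  expect_equal(mueller_rotator(30) %*% mueller_rotator(-30), diag(4),
               tolerance = 1e-12)
})

test_that("retarder matrices reproduce textbook polarization identities", {
  # zero retardance is the identity at any axis
  expect_equal(mueller_retarder(0, 73.2), diag(4), tolerance = 1e-12)
  # half-wave plate at 30 deg maps horizontal (azimuth 0) to azimuth 60
  out <- mueller_retarder(180, 30) %*% c(1, 1, 0, 0)
  expect_equal(drop(out),
               c(1, cos(120 * pi / 180), sin(120 * pi / 180), 0),
               tolerance = 1e-12)
  # quarter-wave plate at 45 deg maps horizontal linear to circular
  out <- mueller_retarder(90, 45) %*% c(1, 1, 0, 0)
  expect_equal(out[1], 1)
  expect_equal(out[2:3], c(0, 0), tolerance = 1e-12)
  expect_equal(abs(out[4]), 1, tolerance = 1e-12)
})

test_that("products of retarders and rotators preserve total intensity", {
  set.seed(11)
  for (i in 1:20) {
    M <- diag(4)
    for (j in 1:5) {
      M <- M %*% if (runif(1) < 0.5) mueller_rotator(runif(1, 0, 360))
      else mueller_retarder(runif(1, 0, 360), runif(1, 0, 180))
    }
    # random physical (fully polarized) Stokes vector
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    S <- c(1, v)
    expect_equal((M %*% S)[1], 1, tolerance = 1e-12)
  }
})

test_that("henle_axis follows the radial geometry about the fovea", {
  expect_equal(henle_axis(0), 0)
  expect_equal(henle_axis(90), 90)   # axis rotates with the scan
  # fovea displaced onto the scan circle: axis from atan2(1.5, -1.5)
  expect_equal(henle_axis(90, offset_deg = c(1.5, 0)), 135)
  expect_error(henle_axis(0, offset_deg = c(1.5, 0)), "invalid geometry")
})

test_that("detector output vanishes without polarization change or reflectance", {
  cfg <- scan_config()
  phi <- seq(0, 359, by = 7.2)
  dark <- eye_optics(corneal_retardance_deg = 0, henle_retardance_deg = 0,
                     depolarized_fraction = 0)
  expect_equal(detector_sample(phi, dark, cfg), rep(0, length(phi)),
               tolerance = 1e-14)
  black <- eye_optics(fundus_reflectance = 0)
  expect_equal(detector_sample(phi, black, cfg), rep(0, length(phi)),
               tolerance = 1e-14)
})

test_that("per-sample energy budget closes", {
  cfg <- scan_config()
  eye <- eye_optics(corneal_retardance_deg = 55, corneal_axis_deg = 40,
                    depolarized_fraction = 0.3)
  comp <- detector_sample(seq(0, 719, by = 1.8), eye, cfg, components = TRUE)
  expect_equal(comp$transmitted + comp$detected_polarized + comp$depolarized,
               comp$reflected, tolerance = 1e-9)
  expect_equal(comp$reflected,
               rep(eye$fundus_reflectance, nrow(comp)), tolerance = 1e-9)
})

test_that("degenerate foveal geometry errors only when the fiber-free core is disabled", {
  cfg <- scan_config()
  on_circle <- eye_optics(fixation_offset_deg = c(1.5, 0))
  expect_silent(detector_sample(c(0, 90), on_circle, cfg))
  no_core <- eye_optics(fixation_offset_deg = c(1.5, 0), foveal_core_deg = 0)
  expect_error(detector_sample(c(0, 90), no_core, cfg), "invalid geometry")
})

test_that("detected signal repeats exactly every two scan revolutions", {
  cfg <- scan_config()
  eye <- eye_optics(corneal_retardance_deg = 63, corneal_axis_deg = 110,
                    fixation_offset_deg = c(0, 1.5))
  full <- detector_sample(scan_angles(cfg)[1:1200], eye, cfg)
  expect_equal(full[401:800], full[1:400], tolerance = 1e-12)
  expect_equal(full[801:1200], full[1:400], tolerance = 1e-12)
})

test_that("harmonic signatures: carrier at 4.5 f_s, sidebands swap with gaze", {
  cfg <- scan_config()
  hh <- c(0.5, 1.5, 2.5, 3.5, 5.5, 6.5, 7.5, 8.5)
  set.seed(21)
  for (i in 1:5) {
    eye <- eye_optics(corneal_retardance_deg = runif(1, 20, 80),
                      corneal_axis_deg = runif(1, 0, 180))
    xc <- phss(detector_sample(scan_angles(cfg), eye, cfg))
    eye$fixation_offset_deg <- c(0, 1.5)
    xo <- phss(detector_sample(scan_angles(cfg), eye, cfg))
    pc <- harm_power(xc, hh, cfg); po <- harm_power(xo, hh, cfg)
    # centered: sidebands at 2.5 and 6.5 dominate the non-carrier power
    expect_gt((pc[3] + pc[6]) / sum(pc), 0.95)
    # para-central: replaced by 3.5 and 5.5
    expect_gt((po[4] + po[5]) / sum(po), 0.95)
    # carrier power practically independent of gaze
    c45 <- harm_power(xc, 4.5, cfg); o45 <- harm_power(xo, 4.5, cfg)
    expect_lt(abs(o45 - c45) / c45, 0.10)
    # and the carrier is the dominant line overall
    expect_gt(c45, max(pc))
  }
})
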