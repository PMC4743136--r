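test_that("effective defocus reproduces the clinical focus arithmetic", {
  # cyclopleged +1.00 D hyperope, 33.3 cm target, +4.00 D lens: best focus
  f <- focus_state(stimulus_vergence_D = 3, refraction_D = 1,
                   lens_power_D = 4, cyclopleged = TRUE)
  expect_equal(effective_defocus(f), 0)
  # same eye, natural viewing with +0.75 D tonic accommodation: +3.25 D lens
  f <- focus_state(stimulus_vergence_D = 3, refraction_D = 1,
                   lens_power_D = 3.25, tonic_D = 0.75)
  expect_equal(effective_defocus(f), 0)
  # all terms zero
  expect_equal(effective_defocus(focus_state(stimulus_vergence_D = 0)), 0)
  # accommodation absorbs demand on the minus-lens side (up to amplitude)
  f <- focus_state(stimulus_vergence_D = 3, refraction_D = 1,
                   lens_power_D = 2, tonic_D = 0.75)
  expect_equal(effective_defocus(f), 0)
})

test_that("defocus split is even, floored at zero, and hits the 0.65 point", {
  expect_lte(defocus_split(0), 0.01)
  expect_equal(defocus_split(1), defocus_split(-1))
  expect_true(all(diff(defocus_split(seq(0, 4, 0.1))) > 0))
  # goodness 1 - 2 f crosses 0.65 at f = 0.175, reached at 1.00 D
  expect_equal(defocus_split(1.0), 0.175, tolerance = 1e-3)
  expect_equal(1 - 2 * defocus_split(1.0), 0.65, tolerance = 2e-3)
})

test_that("records have the documented shape and are seed-deterministic", {
  rec <- synthesize_record(eye_optics(), seed = 42)
  expect_identical(dim(rec$samples), c(4L, 6000L))
  expect_identical(rownames(rec$samples), c("LC", "LA", "RC", "RA"))
  rec2 <- synthesize_record(eye_optics(), seed = 42)
  expect_identical(rec$samples, rec2$samples)
  rec3 <- synthesize_record(eye_optics(), seed = 43)
  expect_false(identical(rec$samples, rec3$samples))
})

test_that("no optics and no noise gives all-zero channels", {
  eye <- eye_optics(corneal_retardance_deg = 0, henle_retardance_deg = 0,
                    depolarized_fraction = 0)
  rec <- synthesize_record(eye, noise = quiet_noise(), seed = 1)
  expect_equal(max(abs(rec$samples)), 0)
})

test_that("center and annulus sum to the defocus-independent total", {
  eye <- eye_optics()
  focused <- synthesize_record(eye, focus_state(stimulus_vergence_D = 0),
                               noise = quiet_noise(), seed = 1)
  blurred <- synthesize_record(
    eye, focus_state(stimulus_vergence_D = 2, cyclopleged = TRUE),
    noise = quiet_noise(), seed = 1)
  expect_gt(max(abs(blurred$samples["LA", ])), 0)  # light did spill over
  expect_equal(blurred$samples["LC", ] + blurred$samples["LA", ],
               focused$samples["LC", ] + focused$samples["LA", ],
               tolerance = 1e-12)
})

test_that("calibration sets have the protocol structure", {
  cal <- make_calibration_set(n_subjects = 1, seed = 3)
  expect_equal(sum(cal$label == "CF"), 24)      # 12 records x 2 eyes
  expect_equal(sum(cal$label == "paraCF"), 96)  # x 4 gaze directions
  expect_true(all(cal$label %in% c("CF", "paraCF")))
  expect_setequal(unique(cal$condition[cal$label == "paraCF"]),
                  c("paraCF-12", "paraCF-3", "paraCF-6", "paraCF-9"))
})

test_that("synthetic CF and para-CF ratios are well separated", {
  cal <- make_calibration_set(n_subjects = 2, seed = 10)
  med_cf <- median(cal$r_cf[cal$label == "CF"])
  med_para <- median(cal$r_cf[cal$label == "paraCF"])
  expect_gt(med_cf, 3 * med_para)
})

test_that("record files round-trip through CSV + JSON", {
  dir <- withr::local_tempdir()
  rec <- synthesize_record(eye_optics(fixation_offset_deg = c(0, 1.5)),
                           seed = 9, subject = "S9", record = 4L)
  path <- file.path(dir, "rec.csv")
  write_record(rec, path)
  back <- read_record(path)
  expect_lt(max(abs(back$samples - rec$samples)) / max(abs(rec$samples)),
            1e-12)
  expect_equal(back$meta$subject, "S9")
  expect_equal(back$meta$offset_left, c(0, 1.5))
  expect_equal(back$cfg$f_s, rec$cfg$f_s)
})

test_that("invalid scan configurations are rejected", {
  expect_error(scan_config(record_seconds = 0.55),
               "integer number of scan revolutions")
  expect_silent(scan_config(record_seconds = 2))
})
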