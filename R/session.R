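## Session- and study-level orchestration: simulate or load 12-record
## sessions, run PhSS -> spectra -> CF/FD decisions, and account
## sensitivity/specificity against a gold standard.

cf_model_from_config <- function(config) {
  switch(config$cf_method,
         threshold = config$cf_theta,
         lda2 = cf_lda_model(config$lda_coefficients$lda2),
         lda3 = cf_lda_model(config$lda_coefficients$lda3),
         lda4 = cf_lda_model(config$lda_coefficients$lda4))
}

#' Simulate a full acquisition session
#'
#' Generates `records_per_session` one-second records for one subject with
#' fixed per-eye optics and accommodative state (one fixed gaze offset per
#' eye for the whole session; eye movement within a session is not
#' modeled).
#'
#' @param eyes list of two [eye_optics()] (or one, used for both eyes).
#' @param focus list of two [focus_state()] (or one).
#' @param config a [study_config()].
#' @param seed session seed; record seeds are derived from it.
#' @param subject subject identifier.
#' @return list of `raw_record` objects.
#' @export
simulate_session <- function(eyes, focus = focus_state(),
                             config = study_config(), seed = 1L,
                             subject = "S1") {
  purrr::map(seq_len(config$records_per_session), function(k) {
    synthesize_record(eyes, focus, config$noise, config$scan,
                      seed = as.integer((as.numeric(seed) * 1009 + k) %% 2147483647),
                      subject = subject, record = k)
  })
}

#' Run the decision pipeline on one session
#'
#' For every record: phase-shift subtraction, per-eye half-harmonic
#' feature extraction and normalization, the configured central-fixation
#' criterion, and the goodness-of-focus criterion. Per eye, the session
#' passes a criterion when at least `k_required` of the records pass
#' (degenerate records are excluded from the numerator but still count in
#' the denominator); proper eye alignment requires simultaneous central
#' fixation of both eyes.
#'
#' All per-record features are retained in the result, so a session can be
#' re-decided later under different rules without re-acquiring data.
#'
#' @param records list of exactly `records_per_session` `raw_record`s.
#' @param config a [study_config()].
#' @return an object of class `session_result`: list with `features`
#'   (per record x eye tibble incl. decisions), `summary` (per-eye tibble)
#'   and the decision flags `cf_left`, `cf_right`, `fd_left`, `fd_right`,
#'   `alignment_pass`.
#' @export
run_session <- function(records, config = study_config()) {
  if (length(records) != config$records_per_session) {
    stop("expected exactly ", config$records_per_session, " records",
         call. = FALSE)
  }
  model <- cf_model_from_config(config)
  feats <- purrr::map(records, function(rec) {
    pr <- phss(rec)
    nf <- normalize_features(
      extract_features(pr, channel = config$channel), on_degenerate = "flag")
    ff <- extract_focus_features(pr)
    nf$cf_pass <- classify_record(nf, model)
    nf$C <- ff$C; nf$A <- ff$A; nf$goodness <- ff$goodness
    nf$fd_pass <- ifelse(is.na(nf$goodness), NA,
                         nf$goodness >= config$fd_threshold)
    nf
  })
  features <- dplyr::bind_rows(feats)
  k <- config$k_required; n <- config$records_per_session
  eye_flag <- function(eye, col) {
    session_decision(features[[col]][features$eye == eye], k = k, n = n)
  }
  cf_l <- eye_flag("left", "cf_pass"); cf_r <- eye_flag("right", "cf_pass")
  fd_l <- eye_flag("left", "fd_pass"); fd_r <- eye_flag("right", "fd_pass")
  summary <- tibble::tibble(
    eye = c("left", "right"),
    cf_pass = c(cf_l, cf_r), fd_pass = c(fd_l, fd_r),
    n_cf_pass = c(sum(features$cf_pass[features$eye == "left"], na.rm = TRUE),
                  sum(features$cf_pass[features$eye == "right"], na.rm = TRUE)),
    n_fd_pass = c(sum(features$fd_pass[features$eye == "left"], na.rm = TRUE),
                  sum(features$fd_pass[features$eye == "right"], na.rm = TRUE)),
    n_usable = c(sum(features$usable[features$eye == "left"]),
                 sum(features$usable[features$eye == "right"])))
  structure(list(features = features, summary = summary,
                 cf_left = cf_l, cf_right = cf_r,
                 fd_left = fd_l, fd_right = fd_r,
                 alignment_pass = cf_l && cf_r,
                 subject = records[[1]]$meta$subject, config = config),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat("<session_result> subject ", x$subject,
      ": CF L/R ", x$cf_left, "/", x$cf_right,
      ", FD L/R ", x$fd_left, "/", x$fd_right,
      ", alignment ", x$alignment_pass, "\n", sep = "")
  invisible(x)
}

offset_vector <- function(magnitude, direction_deg) {
  magnitude * c(cos(direction_deg * pi / 180), sin(direction_deg * pi / 180))
}

simulate_subject_session <- function(row, config, seed) {
  eyes <- purrr::map(c(row$offset_left, row$offset_right), function(mag) {
    eye_optics(
      corneal_retardance_deg = stats::runif(1, 20, 80),
      corneal_axis_deg = stats::runif(1, 0, 180),
      fixation_offset_deg = offset_vector(mag, stats::runif(1, 0, 360)))
  })
  ## refractive error acquired under paralyzed accommodation so the
  ## requested defocus is realized exactly
  focus <- purrr::map(c(row$defocus_left, row$defocus_right), function(d) {
    focus_state(stimulus_vergence_D = 3, lens_power_D = 3, refraction_D = d,
                cyclopleged = TRUE)
  })
  simulate_session(eyes, focus, config, seed = seed, subject = row$subject)
}

#' Run a simulated screening study
#'
#' Takes a subject table with per-eye truth (gaze offset magnitude in
#' degrees and defocus in diopters), simulates and decides one session per
#' subject, and accounts device decisions against the gold standard in the
#' published form: per-function (CF, FD) and pooled (`Both`) confusion
#' counts with sensitivity and specificity. The subject-level device CF
#' decision is eye alignment (both eyes centrally fixating); the FD
#' decision requires both eyes in focus. Gold-standard flags may be
#' supplied as columns `gold_cf`, `gold_fd`; otherwise they are derived
#' from the truth (CF pass iff both offsets are zero; FD pass iff both
#' defocus magnitudes are at most 1 D).
#'
#' @param subjects tibble with columns `subject`, `group` (`"normal"` /
#'   `"patient"`), `offset_left`, `offset_right`, `defocus_left`,
#'   `defocus_right`, and optionally `gold_cf`, `gold_fd`.
#' @param config a [study_config()].
#' @param seed study seed.
#' @return list with `decisions` (per-subject tibble) and `performance`
#'   (per-function evaluation tibble).
#' @export
run_study <- function(subjects, config = study_config(), seed = 1L) {
  stopifnot(nrow(subjects) >= 1)
  if (!"gold_cf" %in% names(subjects)) {
    subjects$gold_cf <- subjects$offset_left == 0 & subjects$offset_right == 0
  }
  if (!"gold_fd" %in% names(subjects)) {
    subjects$gold_fd <- abs(subjects$defocus_left) <= 1 &
      abs(subjects$defocus_right) <= 1
  }
  decisions <- with_seed(seed, {
    purrr::map(seq_len(nrow(subjects)), function(i) {
      row <- subjects[i, ]
      recs <- simulate_subject_session(
        row, config, seed = sample.int(.Machine$integer.max, 1))
      sr <- run_session(recs, config)
      tibble::tibble(subject = row$subject, group = row$group,
                     cf_pass = sr$alignment_pass,
                     fd_pass = sr$fd_left && sr$fd_right,
                     gold_cf = row$gold_cf, gold_fd = row$gold_fd)
    })
  })
  decisions <- dplyr::bind_rows(decisions)
  performance <- study_performance(decisions)
  list(decisions = decisions, performance = performance)
}

#' Tabulate study performance from per-subject decisions
#'
#' @param decisions tibble with `cf_pass`, `fd_pass`, `gold_cf`,
#'   `gold_fd` columns (as produced by [run_study()]).
#' @return tibble with one row per function (`CF`, `FD`, `Both`) of
#'   confusion counts and rates.
#' @export
study_performance <- function(decisions) {
  cf <- evaluate_screening(decisions$cf_pass, decisions$gold_cf)
  fd <- evaluate_screening(decisions$fd_pass, decisions$gold_fd)
  both <- evaluate_screening(c(decisions$cf_pass, decisions$fd_pass),
                             c(decisions$gold_cf, decisions$gold_fd))
  dplyr::bind_rows(CF = cf, FD = fd, Both = both, .id = "criterion")
}
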