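## Plain-text serialization: records as CSV with a JSON sidecar, feature
## tables as CSV, decision models and session summaries as JSON.

#' Write / read a raw record
#'
#' The record samples go to `<path>` as CSV (columns `sample_index`,
#' `ch_LC`, `ch_LA`, `ch_RC`, `ch_RA`, full double precision) and the scan
#' configuration plus metadata (seed, truth labels) to `<path>.json`. The
#' pair round-trips bit-exactly on the JSON and to better than 1e-12
#' relative on the samples.
#'
#' @param rec a `raw_record`.
#' @param path CSV file path; the sidecar is `<path>.json`.
#' @return `write_record` returns `path` invisibly; `read_record` a
#'   `raw_record`.
#' @export
write_record <- function(rec, path) {
  stopifnot(inherits(rec, "raw_record"))
  df <- data.frame(sample_index = seq_len(ncol(rec$samples)) - 1L,
                   ch_LC = rec$samples["LC", ], ch_LA = rec$samples["LA", ],
                   ch_RC = rec$samples["RC", ], ch_RA = rec$samples["RA", ])
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  side <- list(
    cfg = rec$cfg[c("pacing_rate", "steps_per_rev", "hwp_ratio",
                    "scan_radius_deg", "line_freq", "record_seconds")],
    meta = rec$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- do.call(scan_config, as.list(side$cfg))
  samples <- t(as.matrix(df[, c("ch_LC", "ch_LA", "ch_RC", "ch_RA")]))
  rownames(samples) <- c("LC", "LA", "RC", "RA")
  meta <- side$meta
  structure(list(samples = unname(samples) |>
                   `dimnames<-`(list(c("LC", "LA", "RC", "RA"), NULL)),
                 cfg = cfg, meta = meta),
            class = "raw_record")
}

#' Write a feature table to CSV
#'
#' @param features feature tibble (see [make_calibration_set()]).
#' @param path output CSV path.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a fitted central-fixation model as JSON
#'
#' Stores the method, its parameters (threshold or discriminant
#' coefficients), the calibration grid and provenance.
#'
#' @param model a `cf_threshold` or `cf_lda`.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "cf_threshold")) {
    obj <- list(method = "threshold", theta = model$theta,
                objective = model$objective, grid = as.list(model$grid),
                n_cf = model$n_cf, n_para = model$n_para)
  } else if (inherits(model, "cf_lda")) {
    obj <- list(method = paste0("lda", model$dims), dims = model$dims,
                K = model$K, L = model$L, a = as.list(model$a),
                features = model$features, flip = model$flip,
                priors = model$priors)
  } else stop("unsupported model class", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$method, "threshold")) {
    structure(list(theta = obj$theta, objective = obj$objective,
                   grid = unlist(obj$grid), n_cf = obj$n_cf,
                   n_para = obj$n_para, trace = NULL),
              class = "cf_threshold")
  } else {
    m <- cf_lda_model(unlist(obj$a), dims = obj$dims)
    m$K <- obj$K; m$L <- obj$L; m$flip <- isTRUE(obj$flip)
    m
  }
}

#' Export a session result
#'
#' Writes the per-record decision table (one row per record per eye with
#' the four pass/fail flags, mirroring the instrument's results window) to
#' `<path>.csv` and the session summary to `<path>.json`.
#'
#' @param sr a `session_result`.
#' @param path output path prefix.
#' @export
write_session_result <- function(sr, path) {
  stopifnot(inherits(sr, "session_result"))
  utils::write.csv(sr$features, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(subject = sr$subject, cf_left = sr$cf_left, cf_right = sr$cf_right,
         fd_left = sr$fd_left, fd_right = sr$fd_right,
         alignment_pass = sr$alignment_pass),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a focus curve
#'
#' CSV of `(lens_power_D, goodness, mode)` plus a JSON summary with the
#' peak and threshold-crossing lens powers.
#'
#' @param fc a `focus_curve`.
#' @param path output path prefix.
#' @export
write_focus_curve <- function(fc, path) {
  stopifnot(inherits(fc, "focus_curve"))
  utils::write.csv(fc[, c("lens_power_D", "goodness", "mode")],
                   paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(peak_lens_D = attr(fc, "peak_lens_D"),
         crossing_lens_D = attr(fc, "crossing_lens_D"),
         threshold = attr(fc, "threshold")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
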