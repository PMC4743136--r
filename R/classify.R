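#' Calibrate the scalar central-fixation threshold
#'
#' Sweeps a decision threshold over a fixed grid (default 0.3 to 8.00 in
#' steps of 0.001) and, at each level, accumulates the L1 calibration
#' errors `E_CF = sum |r_j - theta|` over the central-fixation set and
#' `E_paraCF` likewise over the para-central set. The returned threshold
#' minimizes the total `E_CF + E_paraCF`; ties are broken toward the
#' smallest threshold. Because the objective is the pooled L1 distance, its
#' minimizer is the grid point nearest the pooled median of all ratios
#' (clamped to the grid) -- it separates the classes only when the data do.
#'
#' `objective = "misclass"` instead minimizes the misclassification count
#' on the same grid (counting a CF value at or below the threshold and a
#' para-CF value above it as errors); this is an alternative criterion, not
#' the published one.
#'
#' @param cf_values numeric `(P2.5 + P6.5)/P4.5` ratios of the CF set.
#' @param para_values ratios of the para-CF set.
#' @param grid_min,grid_max,grid_step threshold grid.
#' @param objective `"l1"` (published) or `"misclass"`.
#' @return an object of class `cf_threshold` with elements `theta`,
#'   `objective`, `grid` and `trace` (tibble of per-level errors).
#' @export
sweep_threshold <- function(cf_values, para_values, grid_min = 0.3,
                            grid_max = 8.0, grid_step = 0.001,
                            objective = c("l1", "misclass")) {
  objective <- match.arg(objective)
  cf_values <- cf_values[is.finite(cf_values)]
  para_values <- para_values[is.finite(para_values)]
  if (!length(cf_values) || !length(para_values)) {
    stop("both calibration sets must be non-empty", call. = FALSE)
  }
  grid <- seq(grid_min, grid_max, by = grid_step)
  if (objective == "l1") {
    ## E(theta) = sum |v - theta| is piecewise linear in theta: evaluate
    ## via sorted cumulative sums rather than an outer() of 7701 x n.
    l1_err <- function(v) {
      v <- sort(v)
      cs <- cumsum(v); tot <- cs[length(v)]
      k <- findInterval(grid, v)
      below <- ifelse(k > 0, cs[pmax(k, 1)], 0)
      k * grid - below + (tot - below) - (length(v) - k) * grid
    }
    e_cf <- l1_err(cf_values)
    e_para <- l1_err(para_values)
  } else {
    e_cf <- purrr::map_dbl(grid, ~ sum(cf_values <= .x))
    e_para <- purrr::map_dbl(grid, ~ sum(para_values > .x))
  }
  total <- e_cf + e_para
  ## smallest theta attaining the minimum, robust to last-digit float noise
  ## in the cumulative-sum evaluation of the piecewise-linear objective
  best <- which(total <= min(total) + 1e-9 * max(1, abs(min(total))))[1]
  structure(list(
    theta = grid[best], objective = objective,
    grid = c(min = grid_min, max = grid_max, step = grid_step),
    n_cf = length(cf_values), n_para = length(para_values),
    trace = tibble::tibble(theta = grid, e_cf = e_cf, e_para = e_para,
                           total = total)),
    class = "cf_threshold")
}

#' @export
print.cf_threshold <- function(x, ...) {
  cat("<cf_threshold> theta = ", format(x$theta), " (", x$objective,
      " objective, ", x$n_cf, " CF / ", x$n_para, " para-CF values)\n",
      sep = "")
  invisible(x)
}

lda_feature_names <- function(dims) {
  switch(as.character(dims),
         "2" = c("r_para", "r_cf"),
         "3" = c("r_para", "r25", "r65"),
         "4" = c("r35", "r55", "r25", "r65"),
         stop("dims must be 2, 3 or 4", call. = FALSE))
}

lda_feature_matrix <- function(features, dims) {
  nm <- lda_feature_names(dims)
  stopifnot(all(nm %in% names(features)))
  as.matrix(features[, nm])
}

#' Fit a linear discriminant central-fixation classifier
#'
#' Two-class linear discriminant with pooled within-class covariance and
#' equal priors (proportional priors optional), fitted on normalized
#' spectral ratios. The boundary is the hyperplane `K + P L' = 0` with
#' `L = S_pooled^-1 (mu_CF - mu_para)` and
#' `K = -(mu_CF + mu_para)' L / 2 + log(prior_CF / prior_para)`; a
#' measurement with `K + P L' > 0` is classified as central fixation.
#' The derived coefficients `a_0 = -K / L(last)`, `a_i = -L(i) / L(last)`
#' express the boundary in the explicit form used by the instrument: in
#' 3D, central fixation iff `r65 > a0 + a1 * r_para + a2 * r25`.
#'
#' Feature maps: 2D `(r_para, r_cf)`; 3D `(r_para, r25, r65)`; 4D
#' `(r35, r55, r25, r65)` (the para-central sum split into its two
#' components). The decision variable is always the last feature.
#'
#' @param features tibble of normalized features (see
#'   [normalize_features()]).
#' @param labels factor/character vector; `"CF"` is the positive class,
#'   anything else is para-central.
#' @param dims 2, 3 or 4.
#' @param priors `"equal"` or `"proportional"`.
#' @param ridge ridge added to the pooled covariance diagonal when it is
#'   numerically singular (an error advises enabling it).
#' @return an object of class `cf_lda` with `K`, `L`, `a`, `dims`, class
#'   means and the pooled covariance.
#' @export
fit_lda <- function(features, labels, dims = 3,
                    priors = c("equal", "proportional"), ridge = 0) {
  priors <- match.arg(priors)
  X <- lda_feature_matrix(features, dims)
  g <- labels == "CF"
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; g <- g[keep]
  n1 <- sum(g); n2 <- sum(!g)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per class", call. = FALSE)
  mu1 <- colMeans(X[g, , drop = FALSE])
  mu2 <- colMeans(X[!g, , drop = FALSE])
  S1 <- stats::cov(X[g, , drop = FALSE])
  S2 <- stats::cov(X[!g, , drop = FALSE])
  Sp <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)
  if (ridge > 0) Sp <- Sp + diag(ridge, ncol(Sp))
  L <- tryCatch(drop(solve(Sp, mu1 - mu2)),
                error = function(e) stop(
                  "pooled covariance is singular; refit with a small `ridge` (e.g. 1e-8)",
                  call. = FALSE))
  K <- -sum((mu1 + mu2) / 2 * L) +
    if (priors == "proportional") log(n1 / n2) else 0
  p <- length(L)
  if (abs(L[p]) < .Machine$double.eps) {
    stop("decision-variable coefficient L(last) is zero; a-form undefined",
         call. = FALSE)
  }
  a <- c(-K / L[p], -L[-p] / L[p])
  names(a) <- paste0("a", seq_along(a) - 1)
  structure(list(K = K, L = unname(L), a = a, dims = dims,
                 features = lda_feature_names(dims),
                 flip = L[p] < 0,   # if TRUE, CF side is r_last < z
                 means = rbind(CF = mu1, paraCF = mu2), pooled_cov = Sp,
                 priors = priors, n = c(CF = n1, paraCF = n2)),
            class = "cf_lda")
}

#' @export
print.cf_lda <- function(x, ...) {
  cat("<cf_lda> ", x$dims, "D discriminant on (",
      paste(x$features, collapse = ", "), ")\n  a = ",
      paste(sprintf("%s = %.4g", names(x$a), x$a), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Build a discriminant model from published a-coefficients
#'
#' Reconstructs a `cf_lda` decision rule directly from the explicit
#' boundary coefficients (decision variable last, unit coefficient):
#' central fixation iff `r_last > a0 + a1 x1 + ...`.
#'
#' @param a numeric vector `(a0, a1, ..., a_{dims-1})`.
#' @param dims discriminant dimensionality; default `length(a)`.
#' @return a `cf_lda` object usable with [classify_record()].
#' @export
cf_lda_model <- function(a, dims = length(a)) {
  stopifnot(length(a) == dims, dims %in% 2:4)
  L <- c(-a[-1], 1)
  structure(list(K = -a[1], L = unname(L),
                 a = stats::setNames(as.numeric(a), paste0("a", seq_len(dims) - 1)),
                 dims = dims, features = lda_feature_names(dims),
                 flip = FALSE, means = NULL, pooled_cov = NULL,
                 priors = "equal", n = NULL),
            class = "cf_lda")
}

#' Classify records as central fixation
#'
#' Applies a fitted decision model to normalized feature rows. For a
#' scalar-threshold model the record passes iff `r_cf > theta` (strict:
#' a value exactly at the threshold fails). For a discriminant model the
#' record passes iff the decision variable exceeds the boundary value
#' `z = a0 + a1 x1 + ...` (e.g. in 3D, `r65 > a0 + a1 r_para + a2 r25`),
#' again strict. Rows flagged unusable (degenerate carrier) return `NA`.
#'
#' @param nf tibble of normalized features, or a single-row tibble.
#' @param model a `cf_threshold`, a bare numeric threshold, or a `cf_lda`.
#' @return logical vector of per-row central-fixation passes.
#' @export
classify_record <- function(nf, model) {
  usable <- if ("usable" %in% names(nf)) nf$usable else rep(TRUE, nrow(nf))
  if (inherits(model, "cf_threshold") || (is.numeric(model) && length(model) == 1L)) {
    theta <- if (is.numeric(model)) model else model$theta
    out <- nf$r_cf > theta
  } else if (inherits(model, "cf_lda")) {
    ## score > 0 is the central-fixation side by construction; when
    ## L(last) > 0 this is identical to the explicit rule r_last > z(a)
    X <- lda_feature_matrix(nf, model$dims)
    score <- model$K + drop(X %*% model$L)
    out <- score > 0
  } else {
    stop("model must be a cf_threshold, numeric threshold, or cf_lda",
         call. = FALSE)
  }
  out[!usable] <- NA
  out
}

#' Session-level k-of-n decision
#'
#' An eye passes the session when at least `k` of its `n` per-record flags
#' pass (2 of 12 at the defaults). `NA` flags (degenerate records) count
#' neither toward the numerator nor reduce the denominator -- conservative
#' toward failing.
#'
#' @param per_record_flags logical vector of per-record passes.
#' @param k required number of passing records.
#' @param n expected number of records.
#' @return single logical.
#' @export
session_decision <- function(per_record_flags, k = 2, n = 12) {
  if (length(per_record_flags) != n) {
    stop("expected exactly ", n, " per-record flags", call. = FALSE)
  }
  sum(per_record_flags, na.rm = TRUE) >= k
}

#' Screening performance against a gold standard
#'
#' Confusion counts and rates with the screening convention that
#' "positive" means abnormal: an eye/subject whose gold standard is *fail*
#' and which the device also fails is a true positive. Sensitivity is
#' `TP / (TP + FN)`, specificity `TN / (TN + FP)`, both in percent; a rate
#' with a zero denominator is reported as `NA`.
#'
#' @param pred_pass logical vector of device pass decisions.
#' @param gold_pass logical vector of gold-standard pass findings.
#' @return one-row tibble with `TN`, `FP`, `TP`, `FN`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_screening <- function(pred_pass, gold_pass) {
  if (length(pred_pass) != length(gold_pass)) {
    stop("prediction and gold-standard vectors differ in length", call. = FALSE)
  }
  tn <- sum(gold_pass & pred_pass, na.rm = TRUE)
  fp <- sum(gold_pass & !pred_pass, na.rm = TRUE)
  tp <- sum(!gold_pass & !pred_pass, na.rm = TRUE)
  fn <- sum(!gold_pass & pred_pass, na.rm = TRUE)
  tibble::tibble(
    TN = tn, FP = fp, TP = tp, FN = fn,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
}
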