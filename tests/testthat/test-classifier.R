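test_that("threshold sweep follows the pooled L1 objective", {
  # larger class dominates: minimum at the lower grid edge
  m <- sweep_threshold(rep(2, 120), rep(0.2, 480))
  expect_equal(m$theta, 0.3)
  # equal-count classes: flat minimum over [0.5, 1.5], tie to the smallest
  m <- sweep_threshold(rep(1.5, 10), rep(0.5, 10))
  expect_equal(m$theta, 0.5)
  # singleton classes at the same value: the pooled median
  m <- sweep_threshold(1.0, 1.0)
  expect_equal(m$theta, 1.0)
})

test_that("sweep matches the brute-force grid oracle and the pooled median", {
  set.seed(77)
  for (i in 1:20) {
    cf <- exp(rnorm(31, 0.5, 0.6))          # odd total count: unique median
    para <- exp(rnorm(30, -1.5, 0.6))
    m <- sweep_threshold(cf, para)
    expect_equal(m$theta, brute_sweep(cf, para), tolerance = 1e-12)
    med <- median(c(cf, para))
    expected <- min(max(round(med, 3), 0.3), 8)  # nearest grid point, clamped
    expect_equal(m$theta, expected, tolerance = 1e-9)
  }
})

test_that("raising the threshold never converts a fail into a pass", {
  set.seed(8)
  r <- exp(rnorm(200))
  nf <- nf_row(r_cf = r)
  thetas <- sort(runif(10, 0.3, 8))
  prev <- classify_record(nf, thetas[1])
  for (th in thetas[-1]) {
    cur <- classify_record(nf, th)
    expect_true(all(prev | !cur))
    prev <- cur
  }
})

test_that("discriminant fit recovers a symmetric boundary", {
  set.seed(42)
  n <- 400
  base <- matrix(rnorm(3 * n, sd = 0.3), n, 3)
  shift <- c(0, 0, 1)   # clouds mirrored about the z = 0.5 plane
  X1 <- sweep(base, 2, shift, "+")
  X2 <- base
  feats <- tibble::as_tibble(rbind(X1, X2), .name_repair = "minimal")
  names(feats) <- c("r_para", "r25", "r65")
  fit <- fit_lda(feats, rep(c("CF", "paraCF"), each = n), dims = 3)
  # boundary normal is along z; plane at z = 0.5
  nvec <- fit$L / sqrt(sum(fit$L^2))
  expect_equal(abs(nvec[3]), 1, tolerance = 0.05)
  expect_equal(fit$a[["a0"]], 0.5, tolerance = 0.05)
  expect_equal(fit$a[["a1"]], 0, tolerance = 0.05)
})

test_that("discriminant decisions agree with the Mahalanobis-distance oracle", {
  set.seed(13)
  n <- 120
  A <- matrix(rnorm(9), 3, 3); Sigma <- crossprod(A) / 3 + diag(0.2, 3)
  mu1 <- c(1, 0.5, 2); mu2 <- c(0.2, 1.2, 0.3)
  Xc <- MASS::mvrnorm(n, mu1, Sigma)
  Xp <- MASS::mvrnorm(n, mu2, Sigma)
  feats <- tibble::as_tibble(rbind(Xc, Xp), .name_repair = "minimal")
  names(feats) <- c("r_para", "r25", "r65")
  labels <- rep(c("CF", "paraCF"), each = n)
  fit <- fit_lda(feats, labels, dims = 3)

  Xnew <- MASS::mvrnorm(50, (mu1 + mu2) / 2, 2 * Sigma)
  newf <- tibble::as_tibble(Xnew, .name_repair = "minimal")
  names(newf) <- c("r_para", "r25", "r65")
  pred <- classify_record(newf, fit)

  # oracle: class with the smaller Mahalanobis distance under the pooled
  # covariance (equal priors)
  Sp <- fit$pooled_cov
  m1 <- colMeans(feats[labels == "CF", ])
  m2 <- colMeans(feats[labels == "paraCF", ])
  oracle <- stats::mahalanobis(Xnew, m1, Sp) <
    stats::mahalanobis(Xnew, m2, Sp)
  expect_equal(pred, unname(oracle))
})

test_that("discriminant fit matches the reference LDA implementation", {
  set.seed(99)
  X <- rbind(matrix(rnorm(300, 1), 100, 3), matrix(rnorm(300, -1), 100, 3))
  feats <- tibble::as_tibble(X, .name_repair = "minimal")
  names(feats) <- c("r_para", "r25", "r65")
  labels <- rep(c("CF", "paraCF"), each = 100)
  fit <- fit_lda(feats, labels, dims = 3)
  ref <- MASS::lda(X, grouping = labels, prior = c(0.5, 0.5))
  ref_pred <- predict(ref, X)$class == "CF"
  expect_equal(classify_record(feats, fit), unname(ref_pred))
})

test_that("a-coefficients relate to K and L as published", {
  set.seed(2)
  X <- rbind(matrix(rnorm(60, 1), 20, 3), matrix(rnorm(60, -1), 20, 3))
  feats <- tibble::as_tibble(X, .name_repair = "minimal")
  names(feats) <- c("r_para", "r25", "r65")
  fit <- fit_lda(feats, rep(c("CF", "paraCF"), each = 20), dims = 3)
  expect_equal(fit$a[["a0"]], -fit$K / fit$L[3], tolerance = 1e-12)
  expect_equal(fit$a[["a1"]], -fit$L[1] / fit$L[3], tolerance = 1e-12)
  expect_equal(fit$a[["a2"]], -fit$L[2] / fit$L[3], tolerance = 1e-12)
})

test_that("well-separated points are never misclassified far from the boundary", {
  set.seed(31)
  n <- 300
  X1 <- cbind(rnorm(n, 0, 0.4), rnorm(n, 0, 0.4), rnorm(n, 3, 0.4))
  X2 <- cbind(rnorm(n, 0, 0.4), rnorm(n, 0, 0.4), rnorm(n, 0, 0.4))
  feats <- tibble::as_tibble(rbind(X1, X2), .name_repair = "minimal")
  names(feats) <- c("r_para", "r25", "r65")
  labels <- rep(c("CF", "paraCF"), each = n)
  fit <- fit_lda(feats, labels, dims = 3)
  pred <- classify_record(feats, fit)
  # signed distance to the true boundary z = 1.5, in pooled sd units
  dist <- (feats$r65 - 1.5) / 0.4
  far <- abs(dist) > 3
  expect_true(all(pred[far] == (dist[far] > 0)))
})

test_that("record classification applies the published decision forms", {
  # scalar threshold, strict inequality
  expect_true(classify_record(nf_row(r_cf = 1.0), 0.8750))
  expect_false(classify_record(nf_row(r_cf = 0.8750), 0.8750))
  # 3D discriminant with the published coefficients:
  # z = 0.768 + 0.056 * 0.5 - 0.289 * 1.0 = 0.507
  model <- cf_lda_model(c(0.768, 0.056, -0.289))
  nf <- nf_row(r_para = 0.5, r25 = 1.0, r65 = 1.0)
  expect_true(classify_record(nf, model))
  # exactly on the boundary fails (strict)
  nf_b <- nf_row(r_para = 0.5, r25 = 1.0, r65 = 0.507)
  expect_false(classify_record(nf_b, model))
  # unusable rows propagate NA
  expect_true(is.na(classify_record(nf_row(r_cf = 2, usable = FALSE), 0.875)))
})

test_that("session decisions follow the 2-of-12 rule", {
  expect_true(session_decision(c(rep(TRUE, 2), rep(FALSE, 10))))
  expect_false(session_decision(c(TRUE, rep(FALSE, 11))))
  expect_true(session_decision(rep(TRUE, 12)))
  expect_error(session_decision(rep(TRUE, 11)), "exactly 12")
})

test_that("screening evaluation reproduces published confusion arithmetic", {
  # FD row: TN 17, FP 2, TP 18, FN 0 -> sensitivity 100, specificity 89.5
  pred <- c(rep(TRUE, 17), rep(FALSE, 2), rep(FALSE, 18))
  gold <- c(rep(TRUE, 19), rep(FALSE, 18))
  ev <- evaluate_screening(pred, gold)
  expect_equal(ev$TN, 17); expect_equal(ev$FP, 2)
  expect_equal(ev$TP, 18); expect_equal(ev$FN, 0)
  expect_equal(ev$sensitivity, 100)
  expect_equal(ev$specificity, 89.5, tolerance = 0.05)
  # pooled row: TN 36, FP 2, TP 36, FN 0 -> specificity 94.7
  ev <- evaluate_screening(c(rep(TRUE, 36), rep(FALSE, 2), rep(FALSE, 36)),
                           c(rep(TRUE, 38), rep(FALSE, 36)))
  expect_equal(ev$specificity, 94.7, tolerance = 0.05)
  expect_equal(ev$sensitivity, 100)
  # all correct
  ev <- evaluate_screening(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(c(ev$sensitivity, ev$specificity), c(100, 100))
  # undefined denominator
  ev <- evaluate_screening(c(TRUE, TRUE), c(TRUE, TRUE))
  expect_true(is.na(ev$sensitivity))
})

test_that("models round-trip through JSON", {
  dir <- withr::local_tempdir()
  m <- sweep_threshold(c(1, 2, 3), c(0.1, 0.2))
  p <- file.path(dir, "thr.json")
  write_model(m, p)
  back <- read_model(p)
  expect_equal(back$theta, m$theta)
  lda <- cf_lda_model(c(0.768, 0.056, -0.289))
  p2 <- file.path(dir, "lda.json")
  write_model(lda, p2)
  back2 <- read_model(p2)
  expect_equal(back2$a, lda$a)
  expect_equal(classify_record(nf_row(r_para = 0.5, r25 = 1, r65 = 1), back2),
               TRUE)
})
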