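test_that("MA transform follows the log2 ratio / mean convention", {
  expect_equal(ma_transform(4, 1), tibble::tibble(A = 1, M = 2))
  expect_equal(ma_transform(1, 4)$M, -2) # antisymmetry
  same <- ma_transform(c(2, 8, 32), c(2, 8, 32))
  expect_equal(same$M, c(0, 0, 0))
  expect_error(ma_transform(c(1, -1), c(1, 1)), class = "pbem_domain_error")
  expect_error(ma_transform(1:3, 1:2), class = "pbem_domain_error")
})

test_that("collinear data give a degenerate ellipse, not a crash", {
  x <- c(1, 2, 3, 4, 5)
  el <- pca_ellipse(x, x)
  expect_true(el$degenerate)
  expect_equal(el$eigvals[2], 0)
  expect_equal(2 * el$semi_minor, 0)
  expect_equal(el$slope_major, 1)
  expect_error(t2_scores(x, x, el), class = "pbem_degenerate_input_error")
})

test_that("ellipse eigenstructure matches the closed form of the covariance", {
  # construct data whose sample covariance is exactly [[2,1],[1,2]]
  set.seed(9)
  n <- 400
  Z <- matrix(rnorm(2 * n), n, 2)
  Z <- sweep(Z, 2, colMeans(Z))
  Z <- Z %*% solve(chol(cov(Z))) # exact identity sample covariance
  S_target <- matrix(c(2, 1, 1, 2), 2, 2)
  X <- Z %*% chol(S_target)
  el <- pca_ellipse(X[, 1], X[, 2])
  # eigenvalues of [[2,1],[1,2]] are 3 and 1; axis ratio sqrt(3)
  expect_equal(el$eigvals, c(3, 1), tolerance = 1e-10)
  expect_equal(el$semi_major / el$semi_minor, sqrt(3), tolerance = 1e-10)
  expect_equal(el$slope_major, 1, tolerance = 1e-8)
  expect_equal(el$slope_minor, -1, tolerance = 1e-8)
  expect_equal(el$slope_major * el$slope_minor, -1) # orthogonal axes
  expect_equal(crossprod(el$eigvecs), diag(2), ignore_attr = TRUE, tolerance = 1e-10)
  expect_error(pca_ellipse(1:2, 1:2), class = "pbem_sample_size_error")
})

test_that("T-squared scores equal the brute-force Mahalanobis distance", {
  # identity-covariance sanity case: point 3 units from the mean scores 9
  set.seed(5)
  n <- 500
  Z <- matrix(rnorm(2 * n), n, 2)
  Z <- sweep(Z, 2, colMeans(Z))
  Z <- Z %*% solve(chol(cov(Z)))
  el <- pca_ellipse(Z[, 1], Z[, 2])
  expect_equal(
    t2_scores(el$center[1] + 3, el$center[2], el),
    9,
    tolerance = 1e-10
  )
  expect_equal(t2_scores(el$center[1], el$center[2], el), 0)

  # random covariances vs explicit (x - xbar)' S^-1 (x - xbar)
  for (rep in 1:20) {
    A <- matrix(rnorm(4), 2, 2)
    S <- crossprod(A) + diag(2) * 0.1
    X <- matrix(rnorm(2 * 200), 200, 2) %*% chol(S)
    el <- pca_ellipse(X[, 1], X[, 2])
    Sinv <- solve(cov(X))
    ctr <- colMeans(X)
    brute <- apply(X, 1, function(p) {
      d <- p - ctr
      as.numeric(t(d) %*% Sinv %*% d)
    })
    expect_lt(max(abs(t2_scores(X[, 1], X[, 2], el) - brute)), 1e-10)
  }
})

test_that("ellipse geometry is equivariant under rotation", {
  set.seed(13)
  X <- cbind(rnorm(300, sd = 2), rnorm(300))
  el0 <- pca_ellipse(X[, 1], X[, 2])
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Xr <- X %*% t(R)
  el1 <- pca_ellipse(Xr[, 1], Xr[, 2])
  expect_equal(el1$semi_major, el0$semi_major, tolerance = 1e-8)
  expect_equal(el1$semi_minor, el0$semi_minor, tolerance = 1e-8)
  expect_equal(el1$eigvals, el0$eigvals, tolerance = 1e-8)
  # the major-axis direction rotates with the data
  v0 <- el0$eigvecs[, 1]
  v1 <- el1$eigvecs[, 1]
  expect_equal(abs(sum((R %*% v0) * v1)), 1, tolerance = 1e-8)
  # T-squared scores are rotation invariant
  expect_equal(
    t2_scores(Xr[, 1], Xr[, 2], el1),
    t2_scores(X[, 1], X[, 2], el0),
    tolerance = 1e-8
  )
})

test_that("out-of-control flags require both a large T2 and a low coordinate", {
  set.seed(3)
  X <- matrix(rnorm(2 * 200), 200, 2)
  el <- pca_ellipse(X[, 1], X[, 2])
  lim <- sqrt(el$t2_limit)
  # at the mean: never flagged
  expect_false(flag_outliers(el$center[1], el$center[2], el))
  # far out but both coordinates above their means: not flagged
  expect_false(flag_outliers(
    el$center[1] + 3 * lim, el$center[2] + 3 * lim, el
  ))
  # far out with x1 below its mean: flagged
  expect_true(flag_outliers(
    el$center[1] - 3 * lim, el$center[2], el
  ))
})

test_that("single-array QC reports the four quality parameters", {
  set.seed(17)
  n <- 500
  signal <- rlnorm(n, 5, 1)
  # background identical to signal: perfect correlation, flat degenerate MA
  pt <- probe_table(tibble::tibble(
    probe_id = paste0("p", 1:n),
    sequence = sample_probe_sequences(n, 12, seed = 2),
    signal = signal, background = signal
  ))
  qc <- single_pbm_qc(pt)
  expect_equal(qc$corr_coef, 1)
  expect_equal(qc$minor_axis_length, 0)

  # independent signal and background: near-zero correlation
  pt2 <- probe_table(tibble::tibble(
    probe_id = paste0("p", 1:5000),
    sequence = sample_probe_sequences(5000, 12, seed = 4),
    signal = rlnorm(5000, 5, 1), background = rlnorm(5000, 3, 0.5)
  ))
  qc2 <- single_pbm_qc(pt2)
  expect_lt(abs(qc2$corr_coef), 0.05)
  expect_equal(length(qc2$outlier_flags), qc2$n_points)
  expect_gte(qc2$major_axis_length, qc2$minor_axis_length)

  tiny <- probe_table(tibble::tibble(
    probe_id = c("a", "b"), sequence = c("ACGT", "TTGG"),
    signal = c(1, 2), background = c(1, 2)
  ))
  expect_error(single_pbm_qc(tiny), class = "pbem_sample_size_error")
  no_bg <- toy_probes()
  expect_error(single_pbm_qc(no_bg), class = "pbem_capability_error")
})

test_that("paired QC separates agreement from disagreement", {
  set.seed(23)
  pt <- probe_table(tibble::tibble(
    probe_id = paste0("p", 1:300),
    sequence = sample_probe_sequences(300, 20, seed = 6),
    signal = rlnorm(300, 4, 1)
  ))
  km <- kmer_median_intensities(pt)

  qc_same <- paired_pbm_qc(km, km)
  expect_equal(qc_same$corr_coef, 1)
  expect_equal(qc_same$regression_coef, 1)
  expect_equal(qc_same$minor_axis_length, 0)
  expect_equal(qc_same$mode, "paired_kmer")

  # permuting one side destroys agreement: corr ~ 0, near-circular ellipse
  km_perm <- km
  km_perm$intensity <- sample(km$intensity)
  qc_perm <- paired_pbm_qc(km, km_perm)
  expect_lt(abs(qc_perm$corr_coef), 0.1)
  expect_gt(qc_perm$minor_axis_length / qc_perm$major_axis_length, 0.8)
})

test_that("QC reports tidy into one-row summaries and plots", {
  set.seed(29)
  pt <- probe_table(tibble::tibble(
    probe_id = paste0("p", 1:100),
    sequence = sample_probe_sequences(100, 12, seed = 8),
    signal = rlnorm(100, 5, 1), background = rlnorm(100, 3, 0.4)
  ))
  qc <- single_pbm_qc(pt)
  g <- glance(qc)
  expect_equal(nrow(g), 1)
  expect_named(g, c(
    "mode", "major_axis_length", "minor_axis_length", "corr_coef",
    "regression_coef", "n_points", "n_outliers"
  ))
  aug <- augment(qc)
  expect_equal(nrow(aug), 100)
  p <- autoplot(qc)
  expect_s3_class(p, "ggplot")
})
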