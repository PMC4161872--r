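# PCA quality-control ellipse: covariance eigenstructure, Hotelling T-squared
# control limit, outlier flags.

#' MA transform of paired positive intensities
#'
#' Standard microarray convention: `M = log2(signal) - log2(background)` and
#' `A = (log2(signal) + log2(background)) / 2`.
#'
#' @param signal,background positive vectors of equal length.
#' @return tibble with columns `A` and `M`.
#' @export
#' @examples
#' ma_transform(4, 1) # A = 1, M = 2
ma_transform <- function(signal, background) {
  if (length(signal) != length(background)) {
    abort("signal and background must have equal length", class = "pbem_domain_error")
  }
  check_positive(signal, "signal")
  check_positive(background, "background")
  ls <- log2(signal)
  lb <- log2(background)
  tibble(A = (ls + lb) / 2, M = ls - lb)
}

# Hotelling T-squared control limit for a two-component ellipse. For large n
# the F-based constant converges to the chi-squared quantile, which is used
# beyond n = 5000 for numerical stability (the difference is < 1e-3 there).
t2_control_limit <- function(n, p_tail) {
  if (n > 5000) {
    qchisq(1 - p_tail, df = 2)
  } else {
    2 * (n - 1) * (n + 1) / (n * (n - 2)) * qf(1 - p_tail, 2, n - 2)
  }
}

#' Fit a PCA quality-control ellipse to paired observations
#'
#' Eigendecomposition of the 2x2 sample covariance of `(x1, x2)` defines the
#' ellipse orientation; the Hotelling T-squared control limit at tail
#' probability `p_tail` scales it. The default `p_tail = 0.0027` corresponds
#' to the three-standard-deviation (99.73%) control ellipse. The semi-axis
#' along principal component `i` is `sqrt(l_i * t2_limit)`; reported axis
#' lengths are full axes (twice the semi-axis). The axes intersect at the
#' sample mean; the slope of the major axis is `V21/V11` and of the minor
#' axis `-V11/V21` with `V = U %*% diag(sqrt(l))`.
#'
#' A singular covariance (perfectly collinear data) is not an error: the
#' ellipse degenerates to a segment with minor axis length 0 and is flagged.
#'
#' @param x1,x2 numeric vectors of equal length, n >= 3.
#' @param p_tail tail probability of the control limit.
#' @return an object of class `pbm_ellipse`.
#' @export
pca_ellipse <- function(x1, x2, p_tail = 0.0027) {
  n <- length(x1)
  if (length(x2) != n) {
    abort("x1 and x2 must have equal length", class = "pbem_domain_error")
  }
  if (n < 3) abort("need at least 3 points", class = "pbem_sample_size_error")
  if (any(!is.finite(x1)) || any(!is.finite(x2))) {
    abort("inputs must be finite", class = "pbem_domain_error")
  }
  center <- c(mean(x1), mean(x2))
  S <- stats::cov(cbind(x1, x2))
  eg <- eigen(S, symmetric = TRUE)
  l <- pmax(eg$values, 0) # guard tiny negative rounding
  U <- eg$vectors
  # orient eigenvectors deterministically: first nonzero component positive
  for (j in 1:2) {
    piv <- which(abs(U[, j]) > 1e-12)[1]
    if (!is.na(piv) && U[piv, j] < 0) U[, j] <- -U[, j]
  }
  degenerate <- l[2] <= l[1] * 1e-12
  if (degenerate) l[2] <- 0
  t2_limit <- t2_control_limit(n, p_tail)
  V <- U %*% diag(sqrt(l))
  slope_major <- V[2, 1] / V[1, 1]
  slope_minor <- -V[1, 1] / V[2, 1]
  structure(
    list(
      center = center, eigvals = l, eigvecs = U, cov = S, n = n,
      p_tail = p_tail, t2_limit = t2_limit,
      semi_major = sqrt(l[1] * t2_limit), semi_minor = sqrt(l[2] * t2_limit),
      slope_major = slope_major, slope_minor = slope_minor,
      degenerate = degenerate
    ),
    class = "pbm_ellipse"
  )
}

#' @export
print.pbm_ellipse <- function(x, ...) {
  cat(sprintf(
    "PCA quality-control ellipse (n = %d, %.2f%% limit)\n",
    x$n, 100 * (1 - x$p_tail)
  ))
  cat(sprintf("  center: (%.4g, %.4g)\n", x$center[1], x$center[2]))
  cat(sprintf(
    "  axis lengths (major, minor): %.4g, %.4g\n",
    2 * x$semi_major, 2 * x$semi_minor
  ))
  cat(sprintf("  major-axis slope: %.4g\n", x$slope_major))
  if (x$degenerate) cat("  note: degenerate (collinear data)\n")
  invisible(x)
}

#' @export
glance.pbm_ellipse <- function(x, ...) {
  tibble(
    n = x$n, p_tail = x$p_tail, t2_limit = x$t2_limit,
    major_axis_length = 2 * x$semi_major, minor_axis_length = 2 * x$semi_minor,
    slope_major = x$slope_major, slope_minor = x$slope_minor,
    center_x1 = x$center[1], center_x2 = x$center[2],
    degenerate = x$degenerate
  )
}

#' @export
tidy.pbm_ellipse <- function(x, ...) {
  tibble(
    axis = c("major", "minor"),
    eigenvalue = x$eigvals,
    semi_length = c(x$semi_major, x$semi_minor),
    length = 2 * c(x$semi_major, x$semi_minor),
    slope = c(x$slope_major, x$slope_minor)
  )
}

#' Hotelling T-squared scores against a fitted ellipse
#'
#' The T-squared score of each point is its Mahalanobis distance from the
#' sample mean under the sample covariance, computed through the PCA y-scores
#' (principal components scaled to unit variance), and is invariant under
#' rotation of the coordinates.
#'
#' @param x1,x2 numeric vectors.
#' @param ellipse a `pbm_ellipse`.
#' @return nonnegative numeric vector of T-squared scores.
#' @export
t2_scores <- function(x1, x2, ellipse) {
  if (ellipse$degenerate) {
    abort("covariance is singular; T-squared scores are undefined (minor axis 0)",
      class = "pbem_degenerate_input_error"
    )
  }
  Xc <- cbind(x1 - ellipse$center[1], x2 - ellipse$center[2])
  Z <- Xc %*% ellipse$eigvecs # principal components
  Y <- sweep(Z, 2, sqrt(ellipse$eigvals), "/") # unit-variance y-scores
  rowSums(Y^2)
}

#' Flag observations out of quality control
#'
#' A point is flagged when its T-squared score exceeds the control limit AND
#' at least one of its coordinates lies below the corresponding sample mean
#' (high-signal outliers above both means are not quality failures).
#'
#' @inheritParams t2_scores
#' @return logical vector.
#' @export
flag_outliers <- function(x1, x2, ellipse) {
  if (ellipse$degenerate) {
    # only variation along the major axis is informative; project onto it
    Xc <- cbind(x1 - ellipse$center[1], x2 - ellipse$center[2])
    z1 <- as.vector(Xc %*% ellipse$eigvecs[, 1]) / sqrt(ellipse$eigvals[1])
    t2 <- z1^2
  } else {
    t2 <- t2_scores(x1, x2, ellipse)
  }
  (t2 > ellipse$t2_limit) &
    (x1 < ellipse$center[1] | x2 < ellipse$center[2])
}
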