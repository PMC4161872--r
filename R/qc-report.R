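# Single-array and paired-array quality-control reports.

new_qc_report <- function(points, ellipse, corr, slope, mode) {
  flags <- flag_outliers(points$x1, points$x2, ellipse)
  structure(
    list(
      points = points, ellipse = ellipse,
      major_axis_length = 2 * ellipse$semi_major,
      minor_axis_length = 2 * ellipse$semi_minor,
      corr_coef = corr, regression_coef = slope,
      n_points = nrow(points), outlier_flags = flags, mode = mode
    ),
    class = "pbm_qc"
  )
}

#' @export
print.pbm_qc <- function(x, ...) {
  cat(sprintf(
    "PBM quality report (%s, n = %d)\n",
    x$mode, x$n_points
  ))
  cat(sprintf(
    "  axis lengths (major, minor): %.4g, %.4g\n",
    x$major_axis_length, x$minor_axis_length
  ))
  cat(sprintf("  correlation: %.4g   regression slope: %.4g\n",
    x$corr_coef, x$regression_coef))
  cat(sprintf("  out-of-control points: %d\n", sum(x$outlier_flags)))
  invisible(x)
}

#' @export
glance.pbm_qc <- function(x, ...) {
  tibble(
    mode = x$mode,
    major_axis_length = x$major_axis_length,
    minor_axis_length = x$minor_axis_length,
    corr_coef = x$corr_coef,
    regression_coef = x$regression_coef,
    n_points = x$n_points,
    n_outliers = sum(x$outlier_flags)
  )
}

#' @export
augment.pbm_qc <- function(x, ...) {
  dplyr::mutate(x$points, outlier = x$outlier_flags)
}

#' Quality control of a single PBM from its signal and background
#'
#' Builds the MA scatter of normalized signal versus normalized background
#' intensities, fits the PCA control ellipse to it, and reports the four
#' single-array quality parameters: the ellipse major and minor axis lengths
#' (the dynamic range of the array), the Pearson correlation between
#' normalized signal and normalized background intensities (a high value
#' suggests the array mostly measured background), and the OLS slope of M on
#' A.
#'
#' @param probes a `probe_table` with a `background` column.
#' @param p_tail control-limit tail probability (default 0.0027, the 99.73%
#'   ellipse).
#' @return a `pbm_qc` object; see [glance.pbm_qc()].
#' @export
single_pbm_qc <- function(probes, p_tail = 0.0027) {
  if (!"background" %in% names(probes)) {
    abort("single-array QC needs a background column", class = "pbem_capability_error")
  }
  if (nrow(probes) < 3) abort("need at least 3 probes", class = "pbem_sample_size_error")
  ns <- normalize_intensities(probes$signal)
  nb <- normalize_intensities(probes$background)
  ma <- ma_transform(probes$signal, probes$background)
  ellipse <- pca_ellipse(ma$A, ma$M, p_tail = p_tail)
  corr <- cor(ns, nb)
  slope <- unname(coef(lm(ma$M ~ ma$A))[2])
  new_qc_report(tibble(x1 = ma$A, x2 = ma$M), ellipse, corr, slope, "single_ma")
}

#' Quality control of a paired PBM design from 8-mer median intensities
#'
#' Pairs the two 8-mer tables over their shared canonical k-mers
#' ([match_paired_kmers()]), Z-scores each side, and fits the PCA control
#' ellipse to the scatter. The major axis length reflects the shared dynamic
#' range; the minor axis length the disagreement between the two arrays. A
#' narrow ellipse (small minor axis) indicates a good-quality pair. Also
#' reported: the Pearson correlation and the OLS slope of array 2 on array 1.
#'
#' @param table_a,table_b `kmer_table`s for the two arrays (e.g. training and
#'   testing experiments).
#' @param p_tail control-limit tail probability.
#' @return a `pbm_qc` object.
#' @export
paired_pbm_qc <- function(table_a, table_b, p_tail = 0.0027) {
  paired <- match_paired_kmers(table_a, table_b)
  if (nrow(paired) < 3) abort("need at least 3 shared k-mers", class = "pbem_sample_size_error")
  ellipse <- pca_ellipse(paired$x1, paired$x2, p_tail = p_tail)
  corr <- cor(paired$x1, paired$x2)
  slope <- unname(coef(lm(paired$x2 ~ paired$x1))[2])
  new_qc_report(tibble(x1 = paired$x1, x2 = paired$x2), ellipse, corr, slope,
    "paired_kmer"
  )
}

# Points on the ellipse boundary, for plotting.
ellipse_boundary <- function(ellipse, n = 361) {
  theta <- seq(0, 2 * pi, length.out = n)
  circ <- rbind(cos(theta) * ellipse$semi_major, sin(theta) * ellipse$semi_minor)
  pts <- ellipse$eigvecs %*% circ
  tibble(x1 = pts[1, ] + ellipse$center[1], x2 = pts[2, ] + ellipse$center[2])
}

#' Plot a PBM quality report
#'
#' Scatter of the QC points with the control ellipse, its axes, and
#' out-of-control points highlighted.
#'
#' @param object a `pbm_qc` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pbm_qc <- function(object, ...) {
  pts <- augment(object)
  boundary <- ellipse_boundary(object$ellipse)
  el <- object$ellipse
  axes <- tibble(
    x1 = el$center[1] + c(-1, 1, 0, 0) * el$semi_major * el$eigvecs[1, 1] +
      c(0, 0, -1, 1) * el$semi_minor * el$eigvecs[1, 2],
    x2 = el$center[2] + c(-1, 1, 0, 0) * el$semi_major * el$eigvecs[2, 1] +
      c(0, 0, -1, 1) * el$semi_minor * el$eigvecs[2, 2],
    axis = c("major", "major", "minor", "minor")
  )
  labs <- if (object$mode == "single_ma") {
    c("A (mean log2 intensity)", "M (log2 ratio)")
  } else {
    c("array 1 (Z-scored 8-mer medians)", "array 2 (Z-scored 8-mer medians)")
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x1, y = .data$x2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier), size = 0.6, alpha = 0.6) +
    ggplot2::geom_path(data = boundary, colour = "red") +
    ggplot2::geom_line(
      data = axes, ggplot2::aes(group = .data$axis),
      colour = "red", linewidth = 0.3
    ) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "forestgreen")) +
    ggplot2::labs(x = labs[1], y = labs[2], colour = "out of control") +
    ggplot2::theme_minimal()
}
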