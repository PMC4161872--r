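# The biophysical occupancy model: position-specific binding energies with
# optional adjacent-dinucleotide corrections, Fermi-Dirac binding probability,
# and probe-level predicted intensity.

#' Construct a binding model
#'
#' A binding model is a position-specific energy matrix `E` (L x 4, columns
#' A, C, G, T; lower energy means stronger binding), an optional adjacent
#' dinucleotide correction matrix `D` ((L-1) x 16; row `j` holds the
#' corrections for base pairs at positions `j` and `j+1`, column index
#' `4*code(a) + code(b) + 1` with A,C,G,T coded 0..3), a chemical potential
#' `mu` set by the TF concentration, and the output scale `w1` and bias `b1`
#' that map summed window occupancies to a predicted intensity.
#'
#' @param energy L x 4 numeric matrix of interaction energies.
#' @param dinuc optional (L-1) x 16 matrix of adjacent-pair corrections.
#' @param mu chemical potential: binding probability is 1/2 when the window
#'   energy equals `mu`.
#' @param w1,b1 output scale and bias.
#' @return an object of class `binding_model`.
#' @export
binding_model <- function(energy, dinuc = NULL, mu = 0, w1 = 1, b1 = 0) {
  energy <- as.matrix(energy)
  L <- nrow(energy)
  if (L < 2 || ncol(energy) != 4 || any(!is.finite(energy))) {
    abort("energy must be a finite L x 4 matrix with L >= 2", class = "pbem_domain_error")
  }
  colnames(energy) <- BASES
  if (!is.null(dinuc)) {
    dinuc <- as.matrix(dinuc)
    if (nrow(dinuc) != L - 1 || ncol(dinuc) != 16 || any(!is.finite(dinuc))) {
      abort("dinuc must be a finite (L-1) x 16 matrix", class = "pbem_domain_error")
    }
    colnames(dinuc) <- as.vector(outer(BASES, BASES, function(a, b) paste0(a, b)))
  }
  structure(
    list(energy = energy, dinuc = dinuc, mu = mu, w1 = w1, b1 = b1, L = L),
    class = "binding_model"
  )
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf(
    "binding model: L = %d, %s, mu = %.4g, w1 = %.4g, b1 = %.4g\n",
    x$L, if (is.null(x$dinuc)) "independent" else "dinucleotide-dependent",
    x$mu, x$w1, x$b1
  ))
  cat("energy matrix (A C G T):\n")
  print(round(x$energy, 4))
  invisible(x)
}

#' @export
tidy.binding_model <- function(x, ...) {
  mono <- tibble(
    term = "energy",
    position = rep(seq_len(x$L), times = 4),
    base = rep(BASES, each = x$L),
    estimate = as.vector(x$energy)
  )
  if (!is.null(x$dinuc)) {
    di <- tibble(
      term = "dinuc",
      position = rep(seq_len(x$L - 1), times = 16),
      base = rep(colnames(x$dinuc), each = x$L - 1),
      estimate = as.vector(x$dinuc)
    )
    mono <- dplyr::bind_rows(mono, di)
  }
  dplyr::bind_rows(
    mono,
    tibble(
      term = c("mu", "w1", "b1"), position = NA_integer_, base = NA_character_,
      estimate = c(x$mu, x$w1, x$b1)
    )
  )
}

#' Number of free parameters of a binding model
#'
#' The energy-independent model has `4L + 3` parameters (the energy matrix
#' plus `mu`, `w1`, `b1`); restricting pair corrections to adjacent positions
#' adds `16(L-1)` rather than `16 L^2`.
#'
#' @param L motif length, at least 2.
#' @param dependent include the adjacent dinucleotide block.
#' @return integer parameter count.
#' @export
num_parameters <- function(L, dependent = FALSE) {
  if (L < 2) abort("motif length must be >= 2", class = "pbem_domain_error")
  4L * as.integer(L) + 3L + if (dependent) 16L * (as.integer(L) - 1L) else 0L
}

#' Binding energy of a single window
#'
#' `E(S) = sum_i E[i, S_i] + sum_j D[j, (S_j, S_j+1)]`, the dinucleotide sum
#' omitted for independent models.
#'
#' @param model a `binding_model`.
#' @param window DNA string of length exactly `L`.
#' @return scalar energy.
#' @export
window_energy <- function(model, window) {
  check_dna(window, "window")
  if (nchar(window) != model$L) {
    abort("window length must equal the motif length", class = "pbem_domain_error")
  }
  codes <- match(strsplit(window, "")[[1]], BASES)
  e <- sum(model$energy[cbind(seq_len(model$L), codes)])
  if (!is.null(model$dinuc)) {
    j <- seq_len(model$L - 1)
    pair <- 4L * (codes[j] - 1L) + codes[j + 1L]
    e <- e + sum(model$dinuc[cbind(j, pair)])
  }
  e
}

#' Fermi-Dirac binding probability of a window
#'
#' `P(S) = 1 / (1 + exp(E(S) - mu))`: the two-state occupancy of the site,
#' strictly decreasing in the window energy and numerically safe for large
#' `|E - mu|`.
#'
#' @inheritParams window_energy
#' @return probability in (0, 1).
#' @export
binding_probability <- function(model, window) {
  stats::plogis(model$mu - window_energy(model, window))
}

#' Predicted occupancy of a probe sequence
#'
#' Sums the Fermi-Dirac probability over all windows sliding by one base over
#' the sequence and, when `both_strands` is `TRUE` (the default, since PBM
#' probes are double-stranded), over its reverse complement, then applies the
#' output layer: `Y = w1 * sum(P) + b1`.
#'
#' @inheritParams window_energy
#' @param sequence DNA string with `nchar(sequence) >= L`.
#' @param both_strands include reverse-complement windows.
#' @return scalar predicted intensity.
#' @export
probe_occupancy <- function(model, sequence, both_strands = TRUE) {
  check_dna(sequence, "sequence")
  if (nchar(sequence) < model$L) {
    abort("sequence is shorter than the motif", class = "pbem_domain_error")
  }
  occupancy_sums(model, sequence, both_strands) * model$w1 + model$b1
}

# Summed window probabilities (no output layer), vectorised over sequences of
# possibly different lengths.
occupancy_sums <- function(model, sequences, both_strands = TRUE) {
  out <- numeric(length(sequences))
  for (grp in split(seq_along(sequences), nchar(sequences))) {
    d <- window_design(sequences[grp], model$L,
      both_strands = both_strands,
      dinuc = !is.null(model$dinuc)
    )
    ew <- as.vector(d$X %*% as.vector(t(model$energy)))
    if (!is.null(model$dinuc)) {
      ew <- ew + as.vector(d$Xd %*% as.vector(t(model$dinuc)))
    }
    p <- stats::plogis(model$mu - ew)
    out[grp] <- as.vector(d$agg %*% p)
  }
  out
}

#' Predicted intensities for a probe table
#'
#' Elementwise [probe_occupancy()] in probe order (computed with a shared
#' sparse window design for speed).
#'
#' @param model a `binding_model`.
#' @param probes a `probe_table` or data frame with a `sequence` column.
#' @param both_strands include reverse-complement windows.
#' @return numeric vector, one prediction per probe.
#' @export
predict_intensities <- function(model, probes, both_strands = TRUE) {
  seqs <- if (is.character(probes)) probes else probes$sequence
  if (any(nchar(seqs) < model$L)) {
    abort("all probes must be at least as long as the motif", class = "pbem_domain_error")
  }
  occupancy_sums(model, seqs, both_strands) * model$w1 + model$b1
}

#' Energy level of a motif
#'
#' Summarizes the binding energy level (proportional to the information
#' content of the motif) as `log(-median(negative entries))` of the energy
#' matrix: the log of the absolute median over the negative (binding)
#' energies.
#'
#' @param x a `binding_model` or an L x 4 energy matrix.
#' @return scalar energy level.
#' @export
energy_level <- function(x) {
  E <- if (inherits(x, "binding_model")) x$energy else as.matrix(x)
  neg <- E[E < 0]
  if (length(neg) == 0) {
    abort("energy level is undefined: no negative energies in the matrix",
      class = "pbem_undefined_metric_error"
    )
  }
  log(-median(neg))
}
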