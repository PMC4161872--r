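# Sparse window design matrices. Every window of every probe becomes one row
# of a mononucleotide indicator matrix X (n_windows x 4L) and, for dependent
# models, an adjacent-pair indicator matrix Xd (n_windows x 16(L-1)); `agg`
# (n_probes x n_windows) sums windows back to probes. All of prediction and
# fitting reduces to matrix products with these.

window_design <- function(sequences, L, both_strands = TRUE, dinuc = FALSE) {
  n <- length(sequences)
  lens <- nchar(sequences)
  if (any(lens < L)) {
    abort("sequence shorter than the motif length", class = "pbem_domain_error")
  }
  if (length(unique(lens)) != 1) {
    abort("window_design needs equal-length sequences", class = "pbem_domain_error")
  }
  len <- lens[1]
  codes <- encode_sequences(sequences)
  if (anyNA(codes)) {
    abort("sequences contain non-ACGT characters", class = "pbem_domain_error")
  }
  n_win <- len - L + 1L

  codes_to_W <- function(cm) {
    idx <- outer(seq_len(n_win), 0:(L - 1L), "+") # n_win x L of positions
    A <- array(cm[, as.vector(idx)], dim = c(n, n_win, L))
    matrix(A, n * n_win, L)
  }
  W <- codes_to_W(codes)
  probe <- rep(seq_len(n), times = n_win)
  if (both_strands) {
    W <- rbind(W, codes_to_W(revcomp_codes(codes)))
    probe <- c(probe, probe[seq_len(n * n_win)])
  }
  nw <- nrow(W)

  X <- Matrix::sparseMatrix(
    i = rep(seq_len(nw), L),
    j = as.vector(vapply(seq_len(L), function(l) 4L * (l - 1L) + W[, l] + 1L,
      integer(nw)
    )),
    x = 1, dims = c(nw, 4L * L)
  )
  Xd <- NULL
  if (dinuc && L >= 2) {
    js <- seq_len(L - 1L)
    Xd <- Matrix::sparseMatrix(
      i = rep(seq_len(nw), L - 1L),
      j = as.vector(vapply(js, function(j) {
        16L * (j - 1L) + 4L * W[, j] + W[, j + 1L] + 1L
      }, integer(nw))),
      x = 1, dims = c(nw, 16L * (L - 1L))
    )
  }
  agg <- Matrix::sparseMatrix(
    i = probe, j = seq_len(nw), x = 1,
    dims = c(n, nw)
  )
  list(X = X, Xd = Xd, agg = agg, probe = probe, n_windows = nw, L = L)
}
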