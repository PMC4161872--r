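# Shared fixtures, built in code at test time.

# A tiny deterministic probe table with known sequences and signals.
toy_probes <- function(signals = c(2, 4, 8), background = NULL,
                       seqs = c(
                         "ACGTACGTAC",
                         "TTGCAAGCTT",
                         "GGGTTTCCCA"
                       )) {
  df <- tibble::tibble(
    probe_id = paste0("p", seq_along(seqs)),
    sequence = seqs, signal = signals
  )
  if (!is.null(background)) df$background <- background
  probe_table(df, array_id = "toy")
}

# Write a probe TSV and return its path.
write_probe_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# A fixed small binding model with distinct energies per position.
toy_model <- function(L = 3, dinuc = FALSE) {
  E <- matrix(seq(0, by = 0.25, length.out = 4 * L), L, 4, byrow = TRUE)
  D <- if (dinuc) matrix(seq(-0.3, 0.3, length.out = 16 * (L - 1)), L - 1, 16,
    byrow = TRUE
  )
  binding_model(E, D, mu = 0.5, w1 = 1.5, b1 = -0.2)
}

# Brute-force occupancy: slow, direct nested-loop oracle.
brute_occupancy <- function(model, seq, both_strands = TRUE) {
  strands <- if (both_strands) c(seq, reverse_complement(seq)) else seq
  tot <- 0
  for (s in strands) {
    for (i in seq_len(nchar(s) - model$L + 1)) {
      tot <- tot + binding_probability(model, substr(s, i, i + model$L - 1))
    }
  }
  tot * model$w1 + model$b1
}
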