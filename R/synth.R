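# Synthetic PBM experiments with a known ground-truth binding model, paired
# array designs with controllable quality, clusterable QC feature sets, and
# synthetic peak sets. The test bed for every other module.

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Random probe sequences
#'
#' i.i.d. uniform sequences over A/C/G/T, deterministic given the seed.
#'
#' @param n number of sequences.
#' @param length sequence length (>= 1).
#' @param seed integer seed.
#' @return character vector of length `n`.
#' @export
sample_probe_sequences <- function(n, length = 35, seed = 1) {
  if (n < 1 || length < 1) {
    abort("n and length must be positive", class = "pbem_domain_error")
  }
  with_seed(seed, {
    m <- matrix(sample(BASES, n * length, replace = TRUE), nrow = n)
    apply(m, 1, paste0, collapse = "")
  })
}

#' A realistic ground-truth binding model
#'
#' One consensus base per position at energy zero and mismatch penalties
#' drawn uniformly from `penalty_range` (energies in units of kT), giving a
#' graded ladder of partial-match affinities rather than an all-or-nothing
#' motif. The chemical potential is set `consensus_margin` above the
#' consensus energy, so the consensus site is bound with probability
#' `plogis(consensus_margin)` (about 0.95 at the default 3) and typical
#' random windows are nearly unbound. Optionally one adjacent base pair gets
#' a planted dinucleotide correction.
#'
#' @param motif_length motif length L.
#' @param seed integer seed.
#' @param penalty_range range of the uniform mismatch penalties (kT).
#' @param consensus_margin `mu` minus the consensus window energy (kT).
#' @param dinuc_position,dinuc_pair,dinuc_energy optional planted adjacent
#'   pair: the correction `dinuc_energy` is applied when the two bases of
#'   `dinuc_pair` (e.g. `"CA"`) occur at positions `dinuc_position`,
#'   `dinuc_position + 1`. `NULL` position means no dinucleotide block. With
#'   the default `dinuc_pair = NULL`, the pair is planted on the
#'   second-best base at each of the two positions and those two mismatch
#'   penalties are set to `alt_penalty`, creating a genuine alternative
#'   binding mode (off-consensus bases rescued by the pair energy) — the
#'   interdependence structure a mononucleotide model cannot absorb into
#'   its marginals.
#' @param alt_penalty mismatch penalty of the alternative-mode bases when
#'   the pair is auto-planted.
#' @return a `binding_model`.
#' @export
random_truth_model <- function(motif_length = 8, seed = 7,
                               penalty_range = c(0.5, 2),
                               consensus_margin = 3,
                               dinuc_position = NULL, dinuc_pair = NULL,
                               dinuc_energy = -2, alt_penalty = 0.5) {
  with_seed(seed, {
    L <- as.integer(motif_length)
    consensus <- sample.int(4, L, replace = TRUE)
    E <- matrix(runif(4 * L, penalty_range[1], penalty_range[2]), L, 4)
    E[cbind(seq_len(L), consensus)] <- 0
    D <- NULL
    if (!is.null(dinuc_position)) {
      D <- matrix(0, L - 1, 16)
      if (is.null(dinuc_pair)) {
        second_best <- function(i) order(E[i, ])[2]
        a <- second_best(dinuc_position)
        b <- second_best(dinuc_position + 1)
        E[dinuc_position, a] <- alt_penalty
        E[dinuc_position + 1, b] <- alt_penalty
        codes <- c(a, b) - 1L
      } else {
        codes <- match(strsplit(dinuc_pair, "")[[1]], BASES) - 1L
      }
      D[dinuc_position, 4L * codes[1] + codes[2] + 1L] <- dinuc_energy
    }
    mu <- sum(E[cbind(seq_len(L), consensus)]) + consensus_margin
    binding_model(E, D, mu = mu, w1 = 1, b1 = 0)
  })
}

#' Simulate a PBM experiment from a known model
#'
#' Probe sequences are uniform random; the measured signal is the model's
#' predicted occupancy plus Gaussian noise, generated directly on the
#' normalized (post-log, Z-score-comparable) scale so the table is directly
#' usable for fitting. The background column is independent Gaussian noise
#' plus a small fraction of the signal. With `scale = "raw"` both columns
#' are mapped through `exp(raw_mean + raw_sd * x)` to positive
#' fluorescence-like intensities, whose log Z-score recovers the normalized
#' values up to an affine map.
#'
#' @param truth a `binding_model` (see [random_truth_model()]).
#' @param n_probes number of probes.
#' @param probe_length probe length (default 35, must be >= the motif).
#' @param noise_sd Gaussian noise standard deviation on the normalized
#'   scale.
#' @param seed integer seed.
#' @param scale `"normalized"` (default) or `"raw"`.
#' @param background_frac fraction of signal leaking into the background
#'   column.
#' @param background_sd standard deviation of the independent background
#'   noise.
#' @param raw_mean,raw_sd affine constants of the raw-scale map.
#' @param array_id identifier for the simulated array.
#' @return a `probe_table` with columns `probe_id`, `sequence`, `signal`,
#'   `background`.
#' @export
simulate_pbm <- function(truth, n_probes = 2000, probe_length = 35,
                         noise_sd = 0.2, seed = 1, scale = "normalized",
                         background_frac = 0.1, background_sd = 0.3,
                         raw_mean = 7, raw_sd = 1, array_id = "sim") {
  if (probe_length < truth$L) {
    abort("probe_length must be >= the motif length", class = "pbem_domain_error")
  }
  scale <- match.arg(scale, c("normalized", "raw"))
  seqs <- sample_probe_sequences(n_probes, probe_length, seed = seed)
  Y <- predict_intensities(truth, seqs)
  with_seed(seed + 500000L, {
    signal <- Y + rnorm(n_probes, 0, noise_sd)
    background <- rnorm(n_probes, 0, background_sd) + background_frac * signal
    if (scale == "raw") {
      signal <- exp(raw_mean + raw_sd * signal)
      background <- exp(raw_mean + raw_sd * background)
    }
    df <- tibble(
      probe_id = sprintf("probe_%06d", seq_len(n_probes)),
      sequence = seqs, signal = signal, background = background
    )
    out <- tibble::new_tibble(df, class = "probe_table")
    attr(out, "array_id") <- array_id
    attr(out, "scale") <- scale
    out
  })
}

#' Simulate a paired PBM design of known quality
#'
#' Two arrays on disjoint random probe designs measuring the same
#' ground-truth model. A `"good"` pair differs only by measurement noise and
#' probe context. A `"bad"` pair additionally carries an array-specific
#' multiplicative 8-mer bias on the second array: every canonical 8-mer gets
#' a lognormal measurement-efficiency factor `exp(N(0, array_bias_sd))`, and
#' each binding window's occupancy contribution is scaled by the factor of
#' its own 8-mer before the probe signals are summed. This selectively
#' reorders the binder 8-mers — exactly the structure the paired 8-mer
#' medians share — while leaving the array's overall signal character
#' intact.
#'
#' @inheritParams simulate_pbm
#' @param quality `"good"` or `"bad"`.
#' @param array_bias_sd standard deviation of the per-8-mer log bias; only
#'   used for `"bad"` pairs.
#' @return list with elements `train` and `test`, both `probe_table`s.
#' @export
simulate_paired_pbm <- function(truth, n_probes = 24000, probe_length = 35,
                                noise_sd = 0.2, seed = 1, quality = "good",
                                array_bias_sd = 3) {
  quality <- match.arg(quality, c("good", "bad"))
  a <- simulate_pbm(truth, n_probes, probe_length, noise_sd,
    seed = seed, array_id = "train"
  )
  b <- simulate_pbm(truth, n_probes, probe_length, noise_sd,
    seed = seed + 1000000L, array_id = "test"
  )
  if (quality == "bad") {
    b$signal <- b$signal - predict_intensities(truth, b) +
      biased_occupancy(truth, b$sequence, array_bias_sd, seed + 2000000L)
  }
  list(train = a, test = b)
}

# Occupancy of each sequence with every window's probability scaled by a
# per-8-mer lognormal efficiency factor (the window's canonical central
# 8-mer, or the whole window when the motif is shorter than 8).
biased_occupancy <- function(truth, sequences, array_bias_sd, seed) {
  L <- truth$L
  len <- nchar(sequences[1])
  n_win <- len - L + 1L
  win_kmers <- function(seqs) {
    probe_idx <- rep(seq_along(seqs), times = n_win)
    starts <- rep(seq_len(n_win), each = length(seqs))
    w <- substring(seqs[probe_idx], starts, starts + L - 1L)
    if (L > 8) {
      off <- (L - 8L) %/% 2L
      w <- substring(w, off + 1L, off + 8L)
    }
    w
  }
  fwd <- win_kmers(sequences)
  rev <- win_kmers(reverse_complement(sequences))
  keys <- canonical_kmer(c(fwd, rev))
  d <- window_design(sequences, L,
    both_strands = TRUE,
    dinuc = !is.null(truth$dinuc)
  )
  ew <- as.vector(d$X %*% as.vector(t(truth$energy)))
  if (!is.null(truth$dinuc)) {
    ew <- ew + as.vector(d$Xd %*% as.vector(t(truth$dinuc)))
  }
  p <- stats::plogis(truth$mu - ew)
  uk <- unique(keys)
  factor_k <- with_seed(
    seed,
    setNames(exp(rnorm(length(uk), 0, array_bias_sd)), uk)
  )
  y <- as.vector(d$agg %*% (p * unname(factor_k[keys])))
  y * truth$w1 + truth$b1
}

#' Simulate clusterable QC feature sets with planted labels
#'
#' Two bivariate-normal clusters in (major, minor) axis-length feature space
#' with unit within-cluster standard deviation and centers `separation`
#' apart: the planted "good" cluster has the longer major axis and the
#' shorter minor axis.
#'
#' @param n_items number of items (>= 4).
#' @param separation distance between cluster centers, in within-cluster
#'   standard deviations.
#' @param seed integer seed.
#' @param prop_good fraction of items planted in the good cluster.
#' @return tibble with columns `id`, `major`, `minor`, and the planted
#'   `label` (`"good"`/`"bad"`).
#' @export
simulate_qc_features <- function(n_items, separation, seed = 1,
                                 prop_good = 0.5) {
  if (n_items < 4) abort("need at least 4 items", class = "pbem_domain_error")
  with_seed(seed, {
    n_good <- round(n_items * prop_good)
    lab <- c(rep("good", n_good), rep("bad", n_items - n_good))
    off <- separation / sqrt(2)
    major <- rnorm(n_items, ifelse(lab == "good", off, 0), 1)
    minor <- rnorm(n_items, ifelse(lab == "good", 0, off), 1)
    tibble(
      id = sprintf("item_%03d", seq_len(n_items)),
      major = major, minor = minor, label = lab
    )
  })
}

#' Simulate a peak set with affinity-dependent tag counts
#'
#' Builds a synthetic chromosome, places peaks along it, embeds consensus
#' sites of the model into a subset of peak centers, and draws tag counts
#' increasing with the true peak affinity — a self-contained fixture for the
#' peak-scanning and regression steps.
#'
#' @param model a `binding_model` whose consensus sites are planted.
#' @param n_peaks number of peaks.
#' @param peak_width width of every peak (bp).
#' @param frac_bound fraction of peaks that receive planted sites.
#' @param tags_per_affinity expected extra tags per unit affinity.
#' @param base_tags baseline expected tag count.
#' @param seed integer seed.
#' @return list with `peaks` (tibble `chrom`, `start`, `end`, `tag_count`)
#'   and `genome` (named character vector with one chromosome).
#' @export
simulate_peak_set <- function(model, n_peaks = 300, peak_width = 400,
                              frac_bound = 0.5, tags_per_affinity = 30,
                              base_tags = 5, seed = 1) {
  gap <- 20L
  chrom_len <- n_peaks * (peak_width + gap) + gap
  with_seed(seed, {
    chrom <- paste0(sample(BASES, chrom_len, replace = TRUE), collapse = "")
    consensus <- paste0(BASES[apply(model$energy, 1, which.min)], collapse = "")
    starts <- gap + (seq_len(n_peaks) - 1L) * (peak_width + gap)
    bound <- sample.int(n_peaks, round(frac_bound * n_peaks))
    for (i in bound) {
      n_sites <- sample(1:3, 1)
      for (s in seq_len(n_sites)) {
        pos <- starts[i] + peak_width %/% 2 + sample(-60:60, 1)
        substr(chrom, pos + 1, pos + model$L) <- consensus
      }
    }
    genome <- c(chr_sim = chrom)
    peaks <- tibble(
      chrom = "chr_sim", start = starts, end = starts + peak_width,
      tag_count = 0
    )
    aff <- peak_affinity(peaks, model, genome)$affinity
    lambda <- base_tags + tags_per_affinity * aff
    peaks$tag_count <- stats::rpois(n_peaks, lambda)
    list(peaks = peaks, genome = genome)
  })
}
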