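# Genomic affinity scanning: PWM-to-energy conversion, peak affinities over
# central windows, top/bottom peak selection, and the tag-count regression.

#' Convert a position weight matrix to an energy matrix
#'
#' `E[i,a] = ln((f[i,a] + eps) / (max_b f[i,b] + eps))`: energies are
#' max-normalized log probabilities, so every entry is <= 0 and the consensus
#' base at each position has energy 0. The pseudocount keeps zero
#' probabilities finite.
#'
#' @param pwm L x 4 matrix of base probabilities (rows sum to 1).
#' @param pseudocount small positive constant added before the log.
#' @return an L x 4 energy matrix (columns A,C,G,T).
#' @export
pwm_to_energy <- function(pwm, pseudocount = 1e-6) {
  pwm <- as.matrix(pwm)
  if (ncol(pwm) != 4 || any(pwm < 0) ||
    any(abs(rowSums(pwm) - 1) > 1e-6)) {
    abort("pwm rows must be nonnegative and sum to 1", class = "pbem_domain_error")
  }
  E <- log(sweep(pwm + pseudocount, 1, apply(pwm, 1, max) + pseudocount, "/"))
  colnames(E) <- BASES
  E
}

#' Read a plain-text PWM
#'
#' Whitespace-separated matrix with 4 columns (A C G T), one row per motif
#' position; lines starting with `#` or `>` are skipped.
#'
#' @param path file path.
#' @return L x 4 numeric matrix.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^[#>]", lines)]
  mat <- do.call(rbind, lapply(lines, function(l) {
    as.numeric(strsplit(trimws(l), "[ \t]+")[[1]])
  }))
  if (ncol(mat) != 4 || any(!is.finite(mat))) {
    abort("PWM must have 4 numeric columns (A C G T)", class = "pbem_format_error")
  }
  colnames(mat) <- BASES
  mat
}

#' Read peaks from a BED4 file
#'
#' Tab-separated `chrom start end tag_count` with 0-based half-open
#' coordinates and no header.
#'
#' @param path file path.
#' @return tibble with columns `chrom`, `start`, `end`, `tag_count`.
#' @export
read_peaks <- function(path) {
  df <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "tag_count"),
    col_types = "ciid", progress = FALSE
  )
  if (any(df$end <= df$start)) {
    abort("peaks must satisfy end > start", class = "pbem_format_error")
  }
  df
}

#' Read a FASTA file into a named character vector
#'
#' Uses Biostrings when available, otherwise a minimal plain-text reader.
#'
#' @param path FASTA path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path)
    out <- toupper(as.character(ss))
    names(out) <- sub("\\s.*", "", names(ss))
    return(out)
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste0,
    character(1),
    collapse = ""
  )
  names(seqs) <- sub("^>(\\S+).*", "\\1", lines[hdr])
  toupper(seqs)
}

# Affinity of one DNA segment: summed Fermi-Dirac probabilities over both
# strands with unit output layer; windows containing ambiguity codes are
# skipped.
segment_affinity <- function(model, seg) {
  if (nchar(seg) < model$L) {
    return(0)
  }
  scan_model <- binding_model(model$energy, model$dinuc,
    mu = model$mu,
    w1 = 1, b1 = 0
  )
  if (grepl("[^ACGT]", seg)) {
    # split at ambiguous bases and scan each clean stretch
    parts <- strsplit(gsub("[^ACGT]", " ", seg), " +")[[1]]
    parts <- parts[nchar(parts) >= model$L]
    if (length(parts) == 0) {
      return(0)
    }
    return(sum(vapply(parts, function(p) {
      occupancy_sums(scan_model, p, both_strands = TRUE)
    }, numeric(1))))
  }
  occupancy_sums(scan_model, seg, both_strands = TRUE)
}

#' Predicted binding affinity of peaks
#'
#' For each peak, sums the Fermi-Dirac binding probability over all sliding
#' windows (both strands) of the central `window_bp` bases — the window
#' `[mid - window_bp/2, mid + window_bp/2)` around the peak midpoint
#' `floor((start + end) / 2)`, clipped to the peak — with unit output layer
#' (`w1 = 1`, `b1 = 0`). Peaks shorter than the window are scanned whole;
#' peaks shorter than the motif get affinity 0 with a warning. Windows
#' containing non-ACGT bases are skipped.
#'
#' @param peaks tibble from [read_peaks()].
#' @param model a `binding_model`.
#' @param genome named character vector of chromosome sequences (see
#'   [read_fasta_sequences()]).
#' @param window_bp width of the central window (default 200).
#' @return `peaks` with an added `affinity` column.
#' @export
peak_affinity <- function(peaks, model, genome, window_bp = 200) {
  missing_chrom <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    abort(paste0("chromosome(s) not in genome: ",
      paste(missing_chrom, collapse = ", ")),
      class = "pbem_lookup_error"
    )
  }
  half <- window_bp %/% 2
  aff <- vapply(seq_len(nrow(peaks)), function(i) {
    start <- peaks$start[i]
    end <- peaks$end[i]
    mid <- (start + end) %/% 2
    s <- max(start, mid - half)
    e <- min(end, mid + half)
    chrom_seq <- genome[[peaks$chrom[i]]]
    # 0-based half-open -> 1-based substring
    seg <- substr(chrom_seq, s + 1, e)
    segment_affinity(model, seg)
  }, numeric(1))
  short <- (peaks$end - peaks$start) < model$L
  if (any(short)) {
    warn(sprintf("%d peak(s) shorter than the motif: affinity 0", sum(short)))
  }
  dplyr::mutate(tibble::as_tibble(peaks), affinity = aff)
}

#' Top- and bottom-ranked peaks by tag count
#'
#' Sorts peaks by `tag_count` descending (stable: ties keep input order) and
#' returns the top `n` together with the bottom `n`.
#'
#' @param peaks tibble with a `tag_count` column.
#' @param n number of peaks from each end; `n <= floor(nrow(peaks) / 2)`.
#' @return tibble of `2n` peaks (top block first).
#' @export
top_bottom_selection <- function(peaks, n) {
  if (n > nrow(peaks) %/% 2) {
    abort("n exceeds half the number of peaks", class = "pbem_domain_error")
  }
  if (n == 0) {
    return(peaks[0, , drop = FALSE])
  }
  ord <- order(-peaks$tag_count) # stable in R: ties keep input order
  peaks[c(head(ord, n), tail(ord, n)), , drop = FALSE]
}

#' Regression of tag counts on predicted affinities
#'
#' Ordinary least squares of ChIP-seq tag counts (response) on predicted
#' binding affinities (explanatory) with an intercept; reports the slope,
#' its t-statistic, and the square root of R-squared (for a single
#' explanatory variable this equals the absolute Pearson correlation).
#'
#' @param affinities,tag_counts numeric vectors of equal length (n >= 3).
#' @return one-row tibble with columns `slope`, `t_value`, `r`, `r_squared`,
#'   `p_value`, `n`.
#' @export
affinity_regression <- function(affinities, tag_counts) {
  n <- length(affinities)
  if (n != length(tag_counts) || n < 3) {
    abort("need equal-length vectors with n >= 3", class = "pbem_domain_error")
  }
  if (var(affinities) == 0) {
    abort("affinities have zero variance", class = "pbem_degenerate_input_error")
  }
  fit <- lm(tag_counts ~ affinities)
  sm <- summary(fit)
  tibble(
    slope = unname(coef(fit)[2]),
    t_value = unname(sm$coefficients[2, "t value"]),
    r = sqrt(sm$r.squared),
    r_squared = sm$r.squared,
    p_value = unname(sm$coefficients[2, "Pr(>|t|)"]),
    n = n
  )
}

#' Affinity-versus-tag-count analysis over peak rankings
#'
#' For each requested top-N grouping (plus the matching bottom-N peaks;
#' `NA` means all peaks), regresses tag counts on predicted affinities.
#'
#' @param peaks_aff tibble from [peak_affinity()] (with `affinity` and
#'   `tag_count` columns).
#' @param top_n integer vector of top/bottom sizes; `NA` entries use all
#'   peaks.
#' @return tibble with one row per grouping: `selection`, `n`, `slope`,
#'   `t_value`, `r`, `r_squared`, `p_value`.
#' @export
rank_group_regression <- function(peaks_aff, top_n = c(500, 1000, 2000, NA)) {
  purrr::map_dfr(top_n, function(nn) {
    sub <- if (is.na(nn)) {
      peaks_aff
    } else {
      top_bottom_selection(peaks_aff, min(nn, nrow(peaks_aff) %/% 2))
    }
    res <- affinity_regression(sub$affinity, sub$tag_count)
    dplyr::bind_cols(
      tibble(selection = if (is.na(nn)) "all" else paste0("top", nn)),
      res
    )
  })
}
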