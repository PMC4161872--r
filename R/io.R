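# Probe-table and 8-mer-table input/output plus intensity normalization.

#' Read a PBM probe table
#'
#' Reads a tab-separated probe table with a header. The required columns are
#' `probe_id`, `sequence` and `signal`; `background` is optional. Column names
#' can be remapped through `dialect` for files using different headers.
#' Probes whose sequence contains characters outside `A`/`C`/`G`/`T` (for
#' example `N` ambiguity codes) are dropped with a message, because the energy
#' model has no ambiguity states.
#'
#' @param path path to a tab-separated file.
#' @param dialect named character vector mapping the canonical names
#'   (`probe_id`, `sequence`, `signal`, `background`) to the column names
#'   actually present in the file, e.g. `c(signal = "intensity")`.
#' @param array_id identifier attached to the table (defaults to the file
#'   name without extension).
#' @return a `probe_table`: a tibble with columns `probe_id`, `sequence`,
#'   `signal` and optionally `background`, carrying an `array_id` attribute.
#' @export
read_probe_table <- function(path, dialect = NULL, array_id = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
    progress = FALSE
  )
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (dialect[[canon]] %in% names(df)) {
        names(df)[names(df) == dialect[[canon]]] <- canon
      }
    }
  }
  required <- c("probe_id", "sequence", "signal")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(
      paste0("probe table is missing required column(s): ",
        paste(missing_cols, collapse = ", ")),
      class = "pbem_format_error"
    )
  }
  keep <- intersect(c("probe_id", "sequence", "signal", "background"), names(df))
  df <- df[keep]
  df$sequence <- toupper(df$sequence)
  probe_table(df, array_id = array_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct and validate a probe table
#'
#' @param df data frame with columns `probe_id`, `sequence`, `signal`, and
#'   optionally `background`.
#' @param array_id identifier for the array.
#' @return a validated `probe_table` tibble.
#' @export
probe_table <- function(df, array_id = "array") {
  df <- tibble::as_tibble(df)
  bad <- grepl("[^ACGT]", df$sequence)
  if (any(bad)) {
    inform(sprintf("dropped %d probe(s) with non-ACGT characters", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0) {
    abort("probe table is empty after filtering", class = "pbem_empty_input_error")
  }
  if (anyDuplicated(df$probe_id)) {
    abort("probe_id values must be unique", class = "pbem_format_error")
  }
  check_positive(df$signal, "signal")
  if ("background" %in% names(df)) {
    check_positive(df$background, "background")
  }
  attr(df, "array_id") <- array_id
  class(df) <- c("probe_table", class(df))
  df
}

#' Write a probe table to TSV
#'
#' @param probes a `probe_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  readr::write_tsv(tibble::as_tibble(probes)[intersect(
    c("probe_id", "sequence", "signal", "background"), names(probes)
  )], path, progress = FALSE)
  invisible(path)
}

#' Z-score of log intensities
#'
#' The normalization used throughout: natural log followed by a Z-score with
#' the sample (n - 1) standard deviation. The result has sample mean 0 and
#' sample standard deviation 1 and is invariant to multiplying the input by a
#' positive constant.
#'
#' @param values positive intensities, length at least 2.
#' @return numeric vector of normalized intensities.
#' @export
#' @examples
#' normalize_intensities(c(1, exp(1), exp(2)))
normalize_intensities <- function(values) {
  check_positive(values, "intensity")
  if (length(values) < 2) {
    abort("need at least 2 values to normalize", class = "pbem_domain_error")
  }
  lv <- log(values)
  s <- sd(lv)
  if (!is.finite(s) || s == 0) {
    abort("intensities have zero variance after log", class = "pbem_degenerate_input_error")
  }
  (lv - mean(lv)) / s
}

#' Median intensity per k-mer
#'
#' For every k-mer (canonicalized with its reverse complement when
#' `collapse_rc` is `TRUE`) the median signal over all probes whose sequence
#' contains the k-mer on either strand. Each probe contributes at most once
#' per k-mer. By default probe signals are first passed through
#' [normalize_intensities()]; set `normalize = FALSE` when signals are already
#' on a normalized scale (e.g. simulated tables).
#'
#' @param probes a `probe_table`.
#' @param k k-mer length (default 8, the standard PBM summary).
#' @param collapse_rc collapse each k-mer with its reverse complement.
#' @param normalize apply [normalize_intensities()] to the signal first.
#' @return a `kmer_table`: tibble with columns `kmer` and `intensity`,
#'   carrying the probe table's `array_id`.
#' @export
kmer_median_intensities <- function(probes, k = 8, collapse_rc = TRUE,
                                    normalize = TRUE) {
  lens <- nchar(probes$sequence)
  if (k > min(lens)) {
    abort("k exceeds the shortest probe length", class = "pbem_domain_error")
  }
  sig <- if (normalize) normalize_intensities(probes$signal) else probes$signal
  n_win <- lens - k + 1
  probe_idx <- rep.int(seq_len(nrow(probes)), n_win)
  starts <- unlist(lapply(n_win, seq_len), use.names = FALSE)
  kmers <- substring(probes$sequence[probe_idx], starts, starts + k - 1L)
  if (collapse_rc) kmers <- canonical_kmer(kmers)
  # one contribution per probe per k-mer
  dup <- duplicated(paste0(probe_idx, "\r", kmers))
  df <- tibble(kmer = kmers[!dup], signal = sig[probe_idx[!dup]])
  out <- dplyr::summarise(dplyr::group_by(df, .data$kmer),
    intensity = median(.data$signal), .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$kmer)
  attr(out, "array_id") <- attr(probes, "array_id")
  class(out) <- c("kmer_table", class(out))
  out
}

#' Read / write an 8-mer intensity table
#'
#' Tab-separated with header `kmer` and `intensity`.
#'
#' @param path file path.
#' @param array_id identifier for the array.
#' @return `read_kmer_table()` returns a `kmer_table` tibble;
#'   `write_kmer_table()` returns `path` invisibly.
#' @export
read_kmer_table <- function(path, array_id = NULL) {
  df <- readr::read_tsv(path, col_types = "cd", progress = FALSE)
  if (!all(c("kmer", "intensity") %in% names(df))) {
    abort("k-mer table needs columns 'kmer' and 'intensity'", class = "pbem_format_error")
  }
  if (nrow(df) == 0) abort("k-mer table is empty", class = "pbem_empty_input_error")
  df$kmer <- toupper(df$kmer)
  attr(df, "array_id") <- array_id %||% sub("\\.[^.]*$", "", basename(path))
  class(df) <- c("kmer_table", class(df))
  df
}

#' @rdname read_kmer_table
#' @param table a `kmer_table`.
#' @export
write_kmer_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table)[c("kmer", "intensity")], path,
    progress = FALSE
  )
  invisible(path)
}

#' Pair two 8-mer tables over their shared k-mers
#'
#' Intersects the k-mer keys of two tables (which must have been canonicalized
#' the same way), orders them lexicographically, and re-Z-scores each side
#' after pairing so the two vectors are directly comparable.
#'
#' @param table_a,table_b `kmer_table`s.
#' @param rescore re-Z-score each vector after pairing (default `TRUE`).
#' @return tibble with columns `kmer`, `x1`, `x2`.
#' @export
match_paired_kmers <- function(table_a, table_b, rescore = TRUE) {
  shared <- sort(intersect(table_a$kmer, table_b$kmer))
  if (length(shared) == 0) {
    abort("the two k-mer tables share no keys", class = "pbem_empty_input_error")
  }
  x1 <- table_a$intensity[match(shared, table_a$kmer)]
  x2 <- table_b$intensity[match(shared, table_b$kmer)]
  if (rescore) {
    zs <- function(v) (v - mean(v)) / sd(v)
    x1 <- zs(x1)
    x2 <- zs(x2)
  }
  tibble(kmer = shared, x1 = x1, x2 = x2)
}
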