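# Plain-text PBEM (protein-binding energy matrix) format:
#   #L=<int> mu=<float> w1=<float> b1=<float>
#   L rows of 4 tab-separated energies (A C G T)
#   optionally a line `#dinuc` followed by L-1 rows of 16 energies.

#' Write a binding model to a PBEM text file
#'
#' @param model a `binding_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pbem <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "#L=%d mu=%.17g w1=%.17g b1=%.17g",
    model$L, model$mu, model$w1, model$b1
  ), con)
  writeLines(apply(model$energy, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t")), con)
  if (!is.null(model$dinuc)) {
    writeLines("#dinuc", con)
    writeLines(apply(model$dinuc, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t")), con)
  }
  invisible(path)
}

#' Read a binding model from a PBEM text file
#'
#' @param path path to a PBEM file written by [write_pbem()].
#' @return a `binding_model`.
#' @export
read_pbem <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- lines[1]
  m <- regmatches(hdr, gregexpr("[A-Za-z0-9]+=[-+0-9.eE]+", hdr))[[1]]
  if (length(m) < 4 || !startsWith(hdr, "#")) {
    abort("malformed PBEM header", class = "pbem_format_error")
  }
  kv <- setNames(
    as.numeric(sub(".*=", "", m)),
    sub("=.*", "", m)
  )
  L <- as.integer(kv[["L"]])
  body <- lines[-1]
  parse_rows <- function(rows, ncol) {
    mat <- do.call(rbind, lapply(rows, function(r) as.numeric(strsplit(r, "\t")[[1]])))
    if (ncol(mat) != ncol || any(!is.finite(mat))) {
      abort("malformed PBEM matrix block", class = "pbem_format_error")
    }
    mat
  }
  energy <- parse_rows(body[seq_len(L)], 4)
  dinuc <- NULL
  rest <- body[-seq_len(L)]
  if (length(rest) > 0 && trimws(rest[1]) == "#dinuc") {
    dinuc <- parse_rows(rest[1 + seq_len(L - 1)], 16)
  }
  binding_model(energy, dinuc, mu = kv[["mu"]], w1 = kv[["w1"]], b1 = kv[["b1"]])
}
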