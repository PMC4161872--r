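# Fuzzy neural-gas classification of arrays into quality groups.

#' Standardize a QC feature table
#'
#' Z-scores every feature column (zero mean, unit sample variance), keeping
#' an `id` column untouched.
#'
#' @param features data frame with an `id` column plus numeric feature
#'   columns.
#' @return tibble with the same columns, features standardized.
#' @export
standardize_features <- function(features) {
  features <- tibble::as_tibble(features)
  num <- setdiff(names(features), "id")
  for (cn in num) {
    v <- features[[cn]]
    if (anyNA(v) || any(!is.finite(v))) {
      abort("features must be finite with no missing values", class = "pbem_domain_error")
    }
    s <- sd(v)
    features[[cn]] <- if (s > 0) (v - mean(v)) / s else v - mean(v)
  }
  features
}

#' Fuzzy neural-gas clustering
#'
#' Prototype-based soft clustering in the neural-gas family: in each epoch
#' the prototypes adapt towards every (shuffled) observation with rank-based
#' soft-max weights `h(r) = exp(-r / lambda)`, the neighbourhood range
#' `lambda` annealed geometrically from `lambda0` to `lambda_final`. After
#' adaptation, fuzzy-c-means memberships
#' `u_ij ∝ (1 / d_ij^2)^(1/(m-1))` grade the confidence of each assignment;
#' rows sum to one. Deterministic given `seed`.
#'
#' @param features data frame with an `id` column plus numeric feature
#'   columns (standardized internally).
#' @param k number of prototypes (clusters), default 2.
#' @param seed integer seed.
#' @param epochs adaptation epochs.
#' @param lambda0 initial neighbourhood range (default `k / 2`).
#' @param lambda_final final neighbourhood range.
#' @param fuzzifier fuzzy-c-means exponent m (> 1).
#' @param learning_rate prototype step size.
#' @return an object of class `pbem_clusters`: list with `prototypes`
#'   (k x d), `memberships` (n x k, rows sum to 1), `hard_labels`,
#'   `ids`, `features`.
#' @export
fuzzy_neural_gas <- function(features, k = 2, seed = 1, epochs = 100,
                             lambda0 = k / 2, lambda_final = 0.01,
                             fuzzifier = 2, learning_rate = 0.3) {
  if (nrow(features) < k) {
    abort("need at least k items", class = "pbem_domain_error")
  }
  features <- standardize_features(features)
  ids <- if ("id" %in% names(features)) features$id else as.character(seq_len(nrow(features)))
  Xm <- as.matrix(features[setdiff(names(features), "id")])
  n <- nrow(Xm)
  if (n < k) abort("need at least k items", class = "pbem_domain_error")

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  proto <- Xm[sample.int(n, k), , drop = FALSE]
  for (t in seq_len(epochs)) {
    lambda <- lambda0 * (lambda_final / lambda0)^((t - 1) / max(1, epochs - 1))
    for (i in sample.int(n)) {
      d2 <- rowSums(sweep(proto, 2, Xm[i, ])^2)
      ranks <- rank(d2, ties.method = "first") - 1
      h <- exp(-ranks / lambda)
      proto <- proto + learning_rate * h * (matrix(Xm[i, ],
        nrow = k,
        ncol = ncol(Xm), byrow = TRUE
      ) - proto)
    }
  }

  d2 <- outer(rowSums(Xm^2), rep(1, k)) - 2 * Xm %*% t(proto) +
    outer(rep(1, n), rowSums(proto^2))
  d2 <- pmax(d2, 1e-12) # epsilon guard before inversion
  u <- (1 / d2)^(1 / (fuzzifier - 1))
  u <- u / rowSums(u)
  structure(
    list(
      prototypes = proto, memberships = u,
      hard_labels = max.col(u, ties.method = "first"),
      ids = ids, features = features, k = k
    ),
    class = "pbem_clusters"
  )
}

#' @export
print.pbem_clusters <- function(x, ...) {
  cat(sprintf(
    "fuzzy neural-gas clustering: %d items, k = %d\n",
    length(x$hard_labels), x$k
  ))
  print(table(cluster = x$hard_labels))
  invisible(x)
}

#' @export
tidy.pbem_clusters <- function(x, ...) {
  out <- tibble(
    id = x$ids, cluster = x$hard_labels,
    membership = x$memberships[cbind(seq_along(x$hard_labels), x$hard_labels)]
  )
  if (!is.null(x$quality_map)) {
    out$quality <- x$quality_map[x$hard_labels]
  }
  out
}

#' Consensus of repeated fuzzy neural-gas runs
#'
#' Runs [fuzzy_neural_gas()] `n_runs` times with seeds `base_seed`,
#' `base_seed + 1`, ..., aligns cluster labels across runs by matching
#' prototypes to the first run (greedy nearest-prototype assignment), and
#' gives each item its majority label and its mean (aligned) membership.
#'
#' @inheritParams fuzzy_neural_gas
#' @param n_runs number of runs to average (default 10).
#' @param base_seed seed of the first run.
#' @param ... passed to [fuzzy_neural_gas()].
#' @return a `pbem_clusters` object with the consensus labels and mean
#'   memberships, plus `run_labels` (n x n_runs matrix of aligned labels).
#' @export
consensus_clustering <- function(features, k = 2, n_runs = 10, base_seed = 1,
                                 ...) {
  runs <- lapply(seq_len(n_runs) - 1L, function(off) {
    fuzzy_neural_gas(features, k = k, seed = base_seed + off, ...)
  })
  ref <- runs[[1]]
  n <- length(ref$hard_labels)
  perm_for <- function(run) {
    # greedy prototype matching to the reference run
    cost <- as.matrix(dist(rbind(run$prototypes, ref$prototypes)))[
      seq_len(k), k + seq_len(k), drop = FALSE
    ]
    perm <- integer(k)
    free_r <- seq_len(k)
    free_c <- seq_len(k)
    for (step in seq_len(k)) {
      sub <- cost[free_r, free_c, drop = FALSE]
      pos <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      perm[free_r[pos[1]]] <- free_c[pos[2]]
      free_r <- free_r[-pos[1]]
      free_c <- free_c[-pos[2]]
    }
    perm
  }
  labels <- matrix(0L, n, n_runs)
  mem <- matrix(0, n, k)
  for (j in seq_along(runs)) {
    perm <- perm_for(runs[[j]])
    labels[, j] <- perm[runs[[j]]$hard_labels]
    mem <- mem + runs[[j]]$memberships[, order(perm), drop = FALSE]
  }
  mem <- mem / n_runs
  majority <- apply(labels, 1, function(l) {
    as.integer(names(which.max(table(l))))
  })
  out <- ref
  out$memberships <- mem
  out$hard_labels <- majority
  out$run_labels <- labels
  out
}

#' Label clusters as good or bad quality
#'
#' The cluster with the larger mean major-axis length is labeled `"good"`
#' (long major axis = wide dynamic range); on a tie, the cluster with the
#' smaller mean minor-axis length wins; if both tie, cluster 1 is labeled
#' good with a warning.
#'
#' @param result a `pbem_clusters` object.
#' @param major_axis_column,minor_axis_column names of the feature columns
#'   holding the (standardized) axis lengths.
#' @return `result` with a `quality_map` (cluster index -> "good"/"bad")
#'   attached; [tidy()] then reports a `quality` column.
#' @export
label_quality_groups <- function(result, major_axis_column = "major",
                                 minor_axis_column = "minor") {
  feats <- result$features
  if (!major_axis_column %in% names(feats)) {
    abort(paste0("no feature column '", major_axis_column, "'"),
      class = "pbem_domain_error"
    )
  }
  k <- result$k
  if (k == 1) {
    result$quality_map <- "good"
    return(result)
  }
  mean_major <- vapply(seq_len(k), function(cl) {
    mean(feats[[major_axis_column]][result$hard_labels == cl])
  }, numeric(1))
  good <- which(mean_major == max(mean_major))
  if (length(good) > 1 && minor_axis_column %in% names(feats)) {
    mean_minor <- vapply(good, function(cl) {
      mean(feats[[minor_axis_column]][result$hard_labels == cl])
    }, numeric(1))
    good <- good[which.min(mean_minor)]
  }
  if (length(good) > 1) {
    warn("quality groups tied on both axes; labelling cluster 1 as good")
    good <- 1L
  }
  qm <- rep("bad", k)
  qm[good[1]] <- "good"
  result$quality_map <- qm
  result
}
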