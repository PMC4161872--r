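# Sparse Bayesian learning of binding-model parameters.
#
# The regularized least-squares objective
#   F = beta * E_D + sum_g alpha_g * E_{w,g},
#   E_D = 1/2 sum_i (T_i - Y_i)^2,  E_{w,g} = 1/2 sum_{j in g} w_j^2
# is minimized by resilient backpropagation (Rprop with weight backtracking)
# over the parameter groups {energy matrix, dinucleotide block, chemical
# potential, output layer}, alternating with MacKay evidence-approximation
# updates of the group shrinkage hyperparameters alpha_g and the noise
# precision beta. Groups whose alpha grows past a pruning threshold are
# frozen at zero: the sparse-learning mechanism.

# ---- parameter layout ------------------------------------------------------

make_layout <- function(L, dependent) {
  nE <- 4L * L
  nD <- if (dependent) 16L * (L - 1L) else 0L
  idx_E <- seq_len(nE)
  idx_D <- if (dependent) nE + seq_len(nD) else integer(0)
  base <- nE + nD
  groups <- list(
    energy = idx_E, dinuc = idx_D,
    mu = base + 1L, output = base + c(2L, 3L)
  )
  if (!dependent) groups$dinuc <- NULL
  list(
    L = L, dependent = dependent, n_par = base + 3L,
    idx_E = idx_E, idx_D = idx_D,
    idx_mu = base + 1L, idx_w1 = base + 2L, idx_b1 = base + 3L,
    groups = groups
  )
}

model_to_theta <- function(model, layout) {
  theta <- numeric(layout$n_par)
  theta[layout$idx_E] <- as.vector(t(model$energy))
  if (layout$dependent) theta[layout$idx_D] <- as.vector(t(model$dinuc))
  theta[layout$idx_mu] <- model$mu
  theta[layout$idx_w1] <- model$w1
  theta[layout$idx_b1] <- model$b1
  theta
}

theta_to_model <- function(theta, layout) {
  E <- matrix(theta[layout$idx_E], nrow = layout$L, ncol = 4, byrow = TRUE)
  D <- if (layout$dependent) {
    matrix(theta[layout$idx_D], nrow = layout$L - 1, ncol = 16, byrow = TRUE)
  } else {
    NULL
  }
  binding_model(E, D,
    mu = theta[layout$idx_mu],
    w1 = theta[layout$idx_w1], b1 = theta[layout$idx_b1]
  )
}

#' Hyperparameters of the sparse Bayesian objective
#'
#' `beta` is the noise precision; each `alpha_*` is the shrinkage strength of
#' one parameter group (output layer `{w1, b1}`, chemical potential `mu`,
#' energy matrix, dinucleotide block). Large `alpha` pins a group near zero;
#' small `alpha` lets the data drive it.
#'
#' @param beta noise precision (> 0).
#' @param alpha_output,alpha_mu,alpha_energy,alpha_dinuc group shrinkage
#'   strengths (> 0).
#' @param gammas optional named vector of effective parameter counts, filled
#'   in by [update_hyperparameters()].
#' @return an object of class `pbem_hyper`.
#' @export
hyper_params <- function(beta = 1, alpha_output = 0.01, alpha_mu = 0.01,
                         alpha_energy = 0.01, alpha_dinuc = 0.01,
                         gammas = NULL) {
  stopifnot(beta > 0, alpha_output > 0, alpha_mu > 0, alpha_energy > 0,
    alpha_dinuc > 0)
  structure(
    list(
      beta = beta,
      alpha = c(
        energy = alpha_energy, dinuc = alpha_dinuc,
        mu = alpha_mu, output = alpha_output
      ),
      gammas = gammas
    ),
    class = "pbem_hyper"
  )
}

alpha_per_param <- function(hyper, layout) {
  av <- numeric(layout$n_par)
  for (g in names(layout$groups)) {
    av[layout$groups[[g]]] <- hyper$alpha[[g]]
  }
  av
}

# ---- objective and gradients ----------------------------------------------

# Core evaluation on a prebuilt window design. Returns objective, E_D,
# per-parameter gradient of F, and the forward quantities reused elsewhere.
eval_objective <- function(theta, design, target, layout, hyper,
                           want_grad = TRUE) {
  mu <- theta[layout$idx_mu]
  w1 <- theta[layout$idx_w1]
  b1 <- theta[layout$idx_b1]
  ew <- as.vector(design$X %*% theta[layout$idx_E])
  if (layout$dependent) {
    ew <- ew + as.vector(design$Xd %*% theta[layout$idx_D])
  }
  P <- stats::plogis(mu - ew)
  SP <- as.vector(design$agg %*% P)
  Y <- w1 * SP + b1
  r <- Y - target
  E_D <- 0.5 * sum(r^2)
  av <- alpha_per_param(hyper, layout)
  FF <- hyper$beta * E_D + 0.5 * sum(av * theta^2)
  out <- list(objective = FF, E_D = E_D, Y = Y, P = P, SP = SP, r = r)
  if (want_grad) {
    pp <- P * (1 - P)
    gwin <- -w1 * r[design$probe] * pp # dE_D / dE_window
    gED <- numeric(layout$n_par)
    gED[layout$idx_E] <- as.vector(Matrix::crossprod(design$X, gwin))
    if (layout$dependent) {
      gED[layout$idx_D] <- as.vector(Matrix::crossprod(design$Xd, gwin))
    }
    gED[layout$idx_mu] <- -sum(gwin)
    gED[layout$idx_w1] <- sum(r * SP)
    gED[layout$idx_b1] <- sum(r)
    out$grad <- hyper$beta * gED + av * theta
  }
  out
}

#' Regularized objective of a binding model on a probe table
#'
#' `F = beta * E_D + sum_g alpha_g * E_{w,g}` with `E_D` half the residual
#' sum of squares between probe signals and predicted intensities and
#' `E_{w,g}` half the squared norm of parameter group `g`.
#'
#' @param model a `binding_model`.
#' @param probes a `probe_table` whose `signal` is on the normalized scale.
#' @param hyper a [hyper_params()] object.
#' @param both_strands sum windows over both strands.
#' @return scalar objective value.
#' @export
fit_objective <- function(model, probes, hyper = hyper_params(),
                          both_strands = TRUE) {
  if (nrow(probes) == 0) abort("no probes", class = "pbem_empty_input_error")
  layout <- make_layout(model$L, !is.null(model$dinuc))
  design <- window_design(probes$sequence, model$L,
    both_strands = both_strands, dinuc = layout$dependent
  )
  eval_objective(model_to_theta(model, layout), design, probes$signal,
    layout, hyper,
    want_grad = FALSE
  )$objective
}

#' Analytic gradients of the fit objective
#'
#' Exact derivatives of [fit_objective()] with respect to every model
#' parameter, chained through the Fermi-Dirac window sums. Validated against
#' central finite differences in the test suite.
#'
#' @inheritParams fit_objective
#' @return named numeric vector of gradients, in the order energy matrix
#'   (position-major, A,C,G,T within position), dinucleotide block (if
#'   present), `mu`, `w1`, `b1`.
#' @export
fit_gradients <- function(model, probes, hyper = hyper_params(),
                          both_strands = TRUE) {
  if (nrow(probes) == 0) abort("no probes", class = "pbem_empty_input_error")
  layout <- make_layout(model$L, !is.null(model$dinuc))
  design <- window_design(probes$sequence, model$L,
    both_strands = both_strands, dinuc = layout$dependent
  )
  g <- eval_objective(model_to_theta(model, layout), design, probes$signal,
    layout, hyper,
    want_grad = TRUE
  )$grad
  nm <- character(layout$n_par)
  nm[layout$idx_E] <- paste0(
    "E", rep(seq_len(layout$L), each = 4), rep(BASES, layout$L)
  )
  if (layout$dependent) {
    pairs <- as.vector(t(outer(BASES, BASES, paste0)))
    nm[layout$idx_D] <- paste0(
      "D", rep(seq_len(layout$L - 1), each = 16), rep(pairs, layout$L - 1)
    )
  }
  nm[c(layout$idx_mu, layout$idx_w1, layout$idx_b1)] <- c("mu", "w1", "b1")
  setNames(g, nm)
}

# ---- Rprop -----------------------------------------------------------------

#' One resilient-backpropagation step
#'
#' Sign-based Rprop update with weight backtracking: per-parameter step sizes
#' grow by `eta_plus` while the gradient sign is stable, shrink by
#' `eta_minus` on a sign flip (and the last move of that parameter is
#' reverted), and are clamped to `[delta_min, delta_max]`. The gradient
#' magnitude is ignored.
#'
#' @param params numeric parameter vector.
#' @param grads gradient vector of the same length.
#' @param state optimizer state from a previous call, or `NULL` to
#'   initialize with step size `delta0`.
#' @param delta0,eta_plus,eta_minus,delta_min,delta_max Rprop constants.
#' @return list with elements `params` (updated vector) and `state`.
#' @export
rprop_step <- function(params, grads, state = NULL, delta0 = 0.1,
                       eta_plus = 1.2, eta_minus = 0.5,
                       delta_min = 1e-6, delta_max = 50) {
  n <- length(params)
  if (is.null(state)) {
    state <- list(
      delta = rep(delta0, n), grad_prev = numeric(n), dw_prev = numeric(n)
    )
  }
  s <- sign(grads) * sign(state$grad_prev)
  dw <- numeric(n)

  up <- s > 0
  state$delta[up] <- pmin(state$delta[up] * eta_plus, delta_max)
  dw[up] <- -sign(grads[up]) * state$delta[up]

  flip <- s < 0
  state$delta[flip] <- pmax(state$delta[flip] * eta_minus, delta_min)
  dw[flip] <- -state$dw_prev[flip] # backtrack the previous move
  grads[flip] <- 0 # suppress a second flip next step

  zero <- s == 0
  dw[zero] <- -sign(grads[zero]) * state$delta[zero]

  state$grad_prev <- grads
  state$dw_prev <- dw
  list(params = params + dw, state = state)
}

# ---- evidence approximation ------------------------------------------------

#' Evidence-approximation update of the hyperparameters
#'
#' MacKay updates with a Gauss-Newton approximation to the Hessian of the
#' objective: the effective number of well-determined parameters in group `g`
#' is `gamma_g = N_g - alpha_g * sum_j [H^-1]_jj` over the group, then
#' `alpha_g <- gamma_g / (2 E_{w,g})` and
#' `beta <- (N - sum_g gamma_g) / (2 E_D)`. A group whose weights have
#' collapsed to zero gets `alpha = alpha_prune` and is treated as pruned;
#' `beta` is capped at `beta_max` when the data are fitted exactly.
#'
#' @inheritParams fit_objective
#' @param alpha_prune shrinkage above which a group counts as pruned.
#' @param beta_max cap on the noise precision.
#' @return an updated [hyper_params()] object with `gammas` filled in.
#' @export
update_hyperparameters <- function(model, probes, hyper = hyper_params(),
                                   both_strands = TRUE, alpha_prune = 1e6,
                                   beta_max = 1e8) {
  layout <- make_layout(model$L, !is.null(model$dinuc))
  design <- window_design(probes$sequence, model$L,
    both_strands = both_strands, dinuc = layout$dependent
  )
  theta <- model_to_theta(model, layout)
  update_hyper_engine(theta, design, probes$signal, layout, hyper,
    alpha_prune = alpha_prune, beta_max = beta_max
  )$hyper
}

update_hyper_engine <- function(theta, design, target, layout, hyper,
                                alpha_prune = 1e6, beta_max = 1e8) {
  ev <- eval_objective(theta, design, target, layout, hyper, want_grad = FALSE)
  w1 <- theta[layout$idx_w1]
  pp <- ev$P * (1 - ev$P)
  n <- length(target)

  # Jacobian dY/dtheta for the Gauss-Newton Hessian H = beta J'J + diag(alpha)
  s <- -w1 * pp
  J_E <- as.matrix(design$agg %*% (Matrix::Diagonal(x = s) %*% design$X))
  J <- J_E
  if (layout$dependent) {
    J <- cbind(J, as.matrix(design$agg %*% (Matrix::Diagonal(x = s) %*% design$Xd)))
  }
  J <- cbind(J,
    mu = as.vector(design$agg %*% (w1 * pp)),
    w1 = ev$SP, b1 = rep(1, n)
  )
  av <- alpha_per_param(hyper, layout)
  H <- hyper$beta * crossprod(J) + diag(av, layout$n_par)
  hinv_diag <- tryCatch(diag(chol2inv(chol(H))), error = function(e) diag(solve(H)))

  alpha_new <- hyper$alpha
  gammas <- setNames(numeric(length(layout$groups)), names(layout$groups))
  for (g in names(layout$groups)) {
    idx <- layout$groups[[g]]
    Ng <- length(idx)
    gam <- Ng - hyper$alpha[[g]] * sum(hinv_diag[idx])
    gam <- min(max(gam, 0), Ng)
    gammas[[g]] <- gam
    two_Ew <- sum(theta[idx]^2)
    if (two_Ew < 1e-12) {
      alpha_new[[g]] <- alpha_prune
    } else {
      alpha_new[[g]] <- min(max(gam / two_Ew, 1e-6), alpha_prune)
    }
  }
  beta_new <- if (ev$E_D < 1e-12) beta_max else (n - sum(gammas)) / (2 * ev$E_D)
  beta_new <- min(max(beta_new, 1e-8), beta_max)

  pruned <- setNames(
    vapply(names(layout$groups), function(g) alpha_new[[g]] >= alpha_prune,
      logical(1)
    ),
    names(layout$groups)
  )
  for (g in names(layout$groups)) {
    if (pruned[[g]]) theta[layout$groups[[g]]] <- 0
  }
  hyper$beta <- beta_new
  hyper$alpha <- alpha_new
  hyper$gammas <- gammas
  list(hyper = hyper, theta = theta, pruned = pruned)
}

# Project the dinucleotide block onto the interaction subspace: every
# adjacent-pair 4x4 matrix is doubly centered (rows and columns sum to
# zero). The removed marginal content is exactly what the mononucleotide
# indicators already span, so predictions are unchanged up to a
# reparameterization while the mono/dinuc decomposition becomes
# identifiable.
project_dinuc <- function(theta, layout) {
  if (!layout$dependent) {
    return(theta)
  }
  D <- matrix(theta[layout$idx_D], nrow = layout$L - 1, ncol = 16, byrow = TRUE)
  for (j in seq_len(nrow(D))) {
    M <- matrix(D[j, ], 4, 4, byrow = TRUE) # rows = first base, cols = second
    M <- M - outer(rowMeans(M), rep(1, 4)) - outer(rep(1, 4), colMeans(M)) +
      mean(M)
    D[j, ] <- as.vector(t(M))
  }
  theta[layout$idx_D] <- as.vector(t(D))
  theta
}

# ---- the fit driver --------------------------------------------------------

#' Fit a binding model to PBM probe intensities
#'
#' Sparse Bayesian learning of a binding model of one motif length: from a
#' small random initialization, resilient backpropagation epochs alternate
#' with evidence-approximation hyperparameter updates until the objective
#' stabilizes. Several random restarts are run; the returned models are
#' ranked by final objective and deduplicated (two fits whose aligned energy
#' matrices correlate above `dedup_r` count as one motif), so rank 1 and 2
#' are the first and second motif.
#'
#' @param probes a `probe_table`; `signal` must already be on the normalized
#'   scale (see [normalize_intensities()]).
#' @param motif_length motif length L (>= 2).
#' @param dependent fit the adjacent dinucleotide correction block.
#' @param n_restarts number of random restarts.
#' @param seed integer seed; restart `r` uses `seed + r - 1`.
#' @param max_epochs Rprop epoch cap per restart. The sigmoid scale is
#'   identified only once the fit leaves the quasi-linear regime, which takes
#'   on the order of a thousand epochs; short caps give compressed energy
#'   matrices.
#' @param hyper_update_every epochs between evidence updates.
#' @param tol relative objective change declaring convergence.
#' @param alpha_prune shrinkage threshold freezing a group at zero.
#' @param rprop list of Rprop constants (see [rprop_step()]).
#' @param both_strands sum windows over both strands.
#' @param init_scale half-width of the uniform parameter initialization.
#' @param init_model optional `binding_model` used to initialize the first
#'   restart (remaining restarts stay random). The natural use is fitting a
#'   dependent model warm-started from a fitted independent model: the
#'   dinucleotide block starts at zero on top of the established energy
#'   matrix, so the dependent fit refines rather than rediscovers the
#'   motif.
#' @param alpha_dinuc0 initial shrinkage of the dinucleotide block. The
#'   block is redundant with the energy matrix over marginal effects, and a
#'   symmetric prior would split such effects between the two; starting the
#'   block at zero under a stronger prior makes it carry only genuine
#'   pair interactions.
#' @param dedup_r aligned-energy correlation above which two restarts count
#'   as the same motif.
#' @return an object of class `pbem_fit` with elements `models` (ranked
#'   `binding_model`s), `objective`, `training_error` (E_D), `hyper`,
#'   `traces`, `seeds`, `motif_length`, `dependent`.
#' @export
fit_binding_model <- function(probes, motif_length = 8, dependent = FALSE,
                              n_restarts = 5, seed = 1, max_epochs = 1500,
                              hyper_update_every = 50, tol = 1e-7,
                              alpha_prune = 1e6,
                              rprop = list(
                                delta0 = 0.1, eta_plus = 1.2, eta_minus = 0.5,
                                delta_min = 1e-6, delta_max = 50
                              ),
                              both_strands = TRUE, init_scale = 0.1,
                              init_model = NULL, alpha_dinuc0 = 1,
                              dedup_r = 0.95) {
  if (nrow(probes) == 0) abort("no probes", class = "pbem_empty_input_error")
  target <- probes$signal
  if (sd(target) == 0) {
    abort("probe intensities are constant", class = "pbem_degenerate_input_error")
  }
  layout <- make_layout(as.integer(motif_length), dependent)
  design <- window_design(probes$sequence, layout$L,
    both_strands = both_strands, dinuc = dependent
  )

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))

  restarts <- vector("list", n_restarts)
  for (rs in seq_len(n_restarts)) {
    restart_seed <- seed + rs - 1L
    set.seed(restart_seed)
    theta <- numeric(layout$n_par)
    theta[layout$idx_E] <- runif(length(layout$idx_E), -init_scale, init_scale)
    # the dinucleotide block starts at zero under a strong prior: it is the
    # higher-complexity hypothesis and must earn its parameters through the
    # evidence updates
    theta[layout$idx_w1] <- 1
    if (rs == 1L && !is.null(init_model)) {
      if (init_model$L != layout$L) {
        abort("init_model must have the same motif length", class = "pbem_domain_error")
      }
      theta[layout$idx_E] <- as.vector(t(init_model$energy))
      if (dependent && !is.null(init_model$dinuc)) {
        theta[layout$idx_D] <- as.vector(t(init_model$dinuc))
        theta <- project_dinuc(theta, layout)
      }
      theta[layout$idx_mu] <- init_model$mu
      theta[layout$idx_w1] <- init_model$w1
      theta[layout$idx_b1] <- init_model$b1
    }

    hyper <- hyper_params(alpha_dinuc = if (dependent) alpha_dinuc0 else 0.01)
    state <- NULL
    pruned <- setNames(
      rep(FALSE, length(layout$groups)), names(layout$groups)
    )
    trace <- numeric(0)
    F_prev <- NA_real_
    diverged <- FALSE
    just_updated <- FALSE
    for (epoch in seq_len(max_epochs)) {
      ev <- eval_objective(theta, design, target, layout, hyper)
      if (!is.finite(ev$objective)) {
        diverged <- TRUE
        break
      }
      trace <- c(trace, ev$objective)
      if (!just_updated && is.finite(F_prev) &&
        abs(ev$objective - F_prev) <= tol * max(1, abs(F_prev))) {
        break
      }
      F_prev <- ev$objective
      just_updated <- FALSE

      g <- ev$grad
      if (dependent) g <- project_dinuc(g, layout) # keep D updates in-subspace
      for (gn in names(layout$groups)) {
        if (pruned[[gn]]) g[layout$groups[[gn]]] <- 0
      }
      st <- rprop_step(theta, g, state,
        delta0 = rprop$delta0, eta_plus = rprop$eta_plus,
        eta_minus = rprop$eta_minus, delta_min = rprop$delta_min,
        delta_max = rprop$delta_max
      )
      theta <- project_dinuc(st$params, layout)
      state <- st$state

      if (epoch %% hyper_update_every == 0) {
        up <- update_hyper_engine(theta, design, target, layout, hyper,
          alpha_prune = alpha_prune
        )
        hyper <- up$hyper
        theta <- project_dinuc(up$theta, layout)
        pruned <- pruned | up$pruned[names(pruned)]
        just_updated <- TRUE
      }
    }
    final <- eval_objective(theta, design, target, layout, hyper,
      want_grad = FALSE
    )
    restarts[[rs]] <- list(
      theta = theta, objective = final$objective, E_D = final$E_D,
      hyper = hyper, trace = trace, seed = restart_seed, diverged = diverged
    )
  }

  ok <- !vapply(restarts, `[[`, logical(1), "diverged") &
    vapply(restarts, function(r) is.finite(r$objective), logical(1))
  if (!any(ok)) {
    abort("all restarts diverged (non-finite objective)",
      class = "pbem_fit_failure_error",
      traces = lapply(restarts, `[[`, "trace")
    )
  }
  # rank by training error: each restart ends with its own fitted beta, so
  # final objectives are not comparable across restarts
  restarts <- restarts[ok][order(vapply(restarts[ok], `[[`, numeric(1), "E_D"))]

  # deduplicate motifs: aligned energy correlation above dedup_r is the same motif
  kept <- list()
  for (r in restarts) {
    mdl <- theta_to_model(r$theta, layout)
    dup <- any(vapply(kept, function(k) {
      align_energy_matrices(k$model$energy, mdl$energy)$r > dedup_r
    }, logical(1)))
    if (!dup) kept[[length(kept) + 1]] <- c(r, list(model = mdl))
  }

  structure(
    list(
      models = lapply(kept, `[[`, "model"),
      objective = vapply(kept, `[[`, numeric(1), "objective"),
      training_error = vapply(kept, `[[`, numeric(1), "E_D"),
      hyper = lapply(kept, `[[`, "hyper"),
      traces = lapply(kept, `[[`, "trace"),
      seeds = vapply(kept, `[[`, numeric(1), "seed"),
      motif_length = layout$L, dependent = dependent, n = nrow(probes)
    ),
    class = "pbem_fit"
  )
}

#' @export
print.pbem_fit <- function(x, ...) {
  cat(sprintf(
    "binding-model fit: L = %d, %s, %d distinct motif(s) from %d probes\n",
    x$motif_length, if (x$dependent) "dinucleotide-dependent" else "independent",
    length(x$models), x$n
  ))
  cat(sprintf(
    "  objectives: %s\n",
    paste(sprintf("%.4g", x$objective), collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.pbem_fit <- function(x, rank = 1, ...) {
  tidy(x$models[[rank]])
}

#' @export
glance.pbem_fit <- function(x, ...) {
  tibble(
    motif_length = x$motif_length, dependent = x$dependent,
    n_motifs = length(x$models), n_probes = x$n,
    objective = x$objective[1], training_error = x$training_error[1],
    beta = x$hyper[[1]]$beta,
    epochs = length(x$traces[[1]])
  )
}

#' Plot the optimization trace of a fit
#'
#' @param object a `pbem_fit`.
#' @param ... unused.
#' @return a ggplot object of objective value against epoch, one line per
#'   retained restart.
#' @export
autoplot.pbem_fit <- function(object, ...) {
  df <- purrr::imap_dfr(object$traces, function(tr, i) {
    tibble(restart = factor(i), epoch = seq_along(tr), objective = tr)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$objective,
    colour = .data$restart
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "objective (log scale)") +
    ggplot2::theme_minimal()
}

# ---- alignment and model selection ----------------------------------------

#' Align two energy matrices over window phase and strand
#'
#' Row-centers both matrices (a per-position constant is absorbed by the
#' chemical potential, so only within-position contrasts are identified),
#' then scans relative offsets and the reverse-complement orientation for
#' the Pearson correlation over the overlapping positions.
#'
#' @param e_a,e_b energy matrices (L x 4, columns A,C,G,T; lengths may
#'   differ).
#' @param min_overlap smallest number of overlapping positions scanned.
#' @return list with `r` (best correlation), `shift`, `strand` (`"+"` or
#'   `"-"`).
#' @export
align_energy_matrices <- function(e_a, e_b, min_overlap = 4) {
  center <- function(E) E - rowMeans(E)
  rc <- function(E) E[rev(seq_len(nrow(E))), 4:1, drop = FALSE]
  A <- center(as.matrix(e_a))
  best <- list(r = -Inf, shift = 0L, strand = "+")
  for (strand in c("+", "-")) {
    B <- center(if (strand == "+") as.matrix(e_b) else rc(as.matrix(e_b)))
    for (shift in seq(-(nrow(B) - min_overlap), nrow(A) - min_overlap)) {
      ia <- max(1, 1 + shift):min(nrow(A), nrow(B) + shift)
      ib <- ia - shift
      if (length(ia) < min_overlap) next
      r <- suppressWarnings(cor(as.vector(A[ia, ]), as.vector(B[ib, ])))
      if (is.finite(r) && r > best$r) {
        best <- list(r = r, shift = as.integer(shift), strand = strand)
      }
    }
  }
  best
}

#' Select the best model on held-out probes
#'
#' Evaluates every ranked model of every fit on a held-out probe table and
#' returns the one with the highest Pearson correlation between predicted
#' and measured intensities; ties are broken by smaller motif length, then
#' lower rank.
#'
#' @param fits a single `pbem_fit` or a list of them (e.g. one per motif
#'   length).
#' @param heldout a `probe_table` disjoint from the training probes.
#' @param both_strands sum windows over both strands.
#' @return list with `model`, `motif_length`, `rank`, `correlation`, and
#'   `candidates` (a tibble of every model's held-out correlation).
#' @export
select_model <- function(fits, heldout, both_strands = TRUE) {
  if (inherits(fits, "pbem_fit")) fits <- list(fits)
  if (nrow(heldout) == 0) abort("held-out table is empty", class = "pbem_empty_input_error")
  rows <- purrr::map_dfr(fits, function(f) {
    purrr::imap_dfr(f$models, function(m, rank) {
      pred <- predict_intensities(m, heldout, both_strands = both_strands)
      tibble(
        motif_length = f$motif_length, dependent = f$dependent,
        rank = rank,
        correlation = suppressWarnings(cor(pred, heldout$signal))
      )
    })
  })
  ord <- order(-rows$correlation, rows$motif_length, rows$rank)
  best <- rows[ord[1], ]
  f <- fits[[which(vapply(fits, function(f) {
    f$motif_length == best$motif_length && f$dependent == best$dependent
  }, logical(1)))[1]]]
  list(
    model = f$models[[best$rank]],
    motif_length = best$motif_length, rank = best$rank,
    correlation = best$correlation, candidates = rows
  )
}

#' Fit a grid of motif lengths and select by held-out correlation
#'
#' Convenience driver mirroring the full analysis: fit every length in
#' `motif_lengths` on the training probes and pick the winner on the
#' held-out probes with [select_model()].
#'
#' @inheritParams fit_binding_model
#' @param heldout held-out `probe_table` for selection.
#' @param motif_lengths integer vector of motif lengths to scan.
#' @param ... passed to [fit_binding_model()].
#' @return as [select_model()], with the fit list attached as `fits`.
#' @export
scan_motif_lengths <- function(probes, heldout, motif_lengths = 7:13,
                               dependent = FALSE, seed = 1, ...) {
  fits <- lapply(motif_lengths, function(L) {
    fit_binding_model(probes,
      motif_length = L, dependent = dependent,
      seed = seed, ...
    )
  })
  sel <- select_model(fits, heldout)
  sel$fits <- fits
  sel
}
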