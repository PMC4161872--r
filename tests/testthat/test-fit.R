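test_that("the objective is beta*E_D plus grouped quadratic penalties", {
  # all parameters zero, one probe with signal 2: F = beta * (1/2) * 2^2
  zero <- binding_model(matrix(0, 3, 4), mu = 0, w1 = 0, b1 = 0)
  one_probe <- probe_table(tibble::tibble(
    probe_id = "p1", sequence = "ACGTACGT", signal = 2
  ), )
  hyp <- hyper_params(beta = 1, alpha_output = 1e-6, alpha_mu = 1e-6,
    alpha_energy = 1e-6)
  # zero model predicts 0 except... w1 = 0 so Y = b1 = 0, residual 2
  expect_equal(fit_objective(zero, one_probe, hyp), 2, tolerance = 1e-5)

  # perfect predictions with all parameters zero would give exactly 0;
  # emulate with target 0
  zero_probe <- probe_table(tibble::tibble(
    probe_id = "p1", sequence = "ACGTACGT", signal = 1
  ))
  zero_probe$signal <- 0
  expect_equal(fit_objective(zero, zero_probe, hyp), 0, tolerance = 1e-12)

  # adding w1 = 3 in a group with alpha = 1 adds (1/2) * 9 = 4.5
  w3 <- binding_model(matrix(0, 3, 4), mu = -60, w1 = 3, b1 = 0)
  hyp2 <- hyper_params(beta = 1, alpha_output = 1, alpha_mu = 1e-12,
    alpha_energy = 1e-12)
  # mu = -60 makes every window probability ~ 0, so predictions stay 0
  expect_equal(
    fit_objective(w3, zero_probe, hyp2) -
      fit_objective(binding_model(matrix(0, 3, 4), mu = -60, w1 = 0, b1 = 0),
        zero_probe, hyp2
      ),
    4.5,
    tolerance = 1e-8
  )
})

test_that("analytic gradients match central finite differences", {
  set.seed(41)
  max_rel <- 0
  for (L in c(3, 5, 8)) {
    for (dep in c(FALSE, TRUE)) {
      truth <- random_truth_model(L, seed = L + dep)
      probes <- simulate_pbm(truth,
        n_probes = 50, probe_length = L + 10,
        noise_sd = 0.4, seed = L * 10 + dep
      )
      model <- binding_model(
        matrix(rnorm(4 * L, sd = 0.5), L, 4),
        if (dep) matrix(rnorm(16 * (L - 1), sd = 0.3), L - 1, 16),
        mu = rnorm(1), w1 = runif(1, 0.5, 2), b1 = rnorm(1, sd = 0.2)
      )
      hyp <- hyper_params(
        beta = runif(1, 0.5, 2), alpha_energy = 0.05,
        alpha_dinuc = 0.02, alpha_mu = 0.01, alpha_output = 0.03
      )
      g <- fit_gradients(model, probes, hyp)
      layout <- pbem:::make_layout(L, dep)
      theta <- pbem:::model_to_theta(model, layout)
      h <- 1e-5
      fd <- vapply(seq_along(theta), function(j) {
        tp <- theta
        tp[j] <- tp[j] + h
        tm <- theta
        tm[j] <- tm[j] - h
        (fit_objective(pbem:::theta_to_model(tp, layout), probes, hyp) -
          fit_objective(pbem:::theta_to_model(tm, layout), probes, hyp)) / (2 * h)
      }, numeric(1))
      rel <- max(abs(g - fd)) / max(1e-8, max(abs(fd)))
      max_rel <- max(max_rel, rel)
    }
  }
  expect_lt(max_rel, 1e-5)
})

test_that("gradients collapse through a zero output weight", {
  truth <- random_truth_model(4, seed = 3)
  probes <- simulate_pbm(truth, n_probes = 30, probe_length = 12, seed = 2)
  m0 <- binding_model(matrix(0.3, 4, 4), mu = 0.5, w1 = 0, b1 = 0)
  hyp <- hyper_params(alpha_energy = 0.7)
  g <- fit_gradients(m0, probes, hyp)
  # with w1 = 0 the data term cannot reach E: only the prior term remains
  expect_equal(unname(g[1:16]), rep(0.7 * 0.3, 16))
})

test_that("rprop steps grow on stable signs, backtrack on flips", {
  p <- 0
  g <- 1
  s1 <- rprop_step(p, g, NULL, delta0 = 0.1)
  expect_equal(s1$params, -0.1) # first step at delta0
  s2 <- rprop_step(s1$params, 1, s1$state)
  expect_equal(s2$params, -0.1 - 0.12)
  s3 <- rprop_step(s2$params, 1, s2$state)
  expect_equal(s3$params, -0.1 - 0.12 - 0.144) # delta0 * 1.2^2 on step 3

  # sign flip: step size halves and the last move is reverted
  s4 <- rprop_step(s3$params, -1, s3$state)
  expect_equal(s4$params, s2$params) # backtracked
  expect_equal(s4$state$delta, 0.144 * 0.5)

  # zero gradient: parameter unchanged
  s5 <- rprop_step(5, 0, NULL)
  expect_equal(s5$params, 5)
})

test_that("evidence updates bound gamma and prune collapsed groups", {
  truth <- random_truth_model(4, seed = 9)
  probes <- simulate_pbm(truth, n_probes = 300, probe_length = 14,
    noise_sd = 0.2, seed = 5)
  hyp <- hyper_params()
  up <- update_hyperparameters(truth, probes, hyp)
  sizes <- c(energy = 16, mu = 1, output = 2)
  for (g in names(sizes)) {
    expect_gte(up$gammas[[g]], 0)
    expect_lte(up$gammas[[g]], sizes[[g]])
  }

  # a group already at zero is pruned to alpha_prune
  zero_mu <- binding_model(truth$energy, mu = 0, w1 = truth$w1, b1 = truth$b1)
  up2 <- update_hyperparameters(zero_mu, probes, hyp)
  expect_equal(up2$alpha[["mu"]], 1e6)

  # noiseless data drive beta to its cap
  clean <- simulate_pbm(truth, n_probes = 300, probe_length = 14,
    noise_sd = 0, seed = 5)
  up3 <- update_hyperparameters(truth, clean, hyp)
  expect_gt(up3$beta, 1e3)
})

test_that("fitting is deterministic given the seed", {
  truth <- random_truth_model(5, seed = 21)
  probes <- simulate_pbm(truth, n_probes = 300, probe_length = 20,
    noise_sd = 0.2, seed = 6)
  f1 <- fit_binding_model(probes, motif_length = 5, n_restarts = 2, seed = 3,
    max_epochs = 60)
  f2 <- fit_binding_model(probes, motif_length = 5, n_restarts = 2, seed = 3,
    max_epochs = 60)
  expect_identical(f1$models, f2$models)
  expect_identical(f1$traces, f2$traces)
  f3 <- fit_binding_model(probes, motif_length = 5, n_restarts = 1, seed = 40,
    max_epochs = 60)
  expect_false(identical(f1$models[[1]], f3$models[[1]]))
})

test_that("degenerate inputs fail loudly", {
  flat <- probe_table(tibble::tibble(
    probe_id = paste0("p", 1:10),
    sequence = sample_probe_sequences(10, 12, seed = 2),
    signal = rep(1, 10)
  ))
  expect_error(fit_binding_model(flat, motif_length = 4),
    class = "pbem_degenerate_input_error"
  )
})

test_that("the objective trace trends downward despite Rprop oscillation", {
  truth <- random_truth_model(5, seed = 33)
  probes <- simulate_pbm(truth, n_probes = 400, probe_length = 20,
    noise_sd = 0.2, seed = 8)
  fit <- fit_binding_model(probes, motif_length = 5, n_restarts = 1, seed = 1,
    max_epochs = 200)
  tr <- fit$traces[[1]]
  expect_lt(tr[length(tr)], tr[1] * 0.1)
  # within the first hyperparameter window the objective is comparable
  # across epochs and its running minimum must fall steeply
  expect_lt(min(tr[2:50]), tr[1] * 0.1)
})

test_that("a short fit recovers a planted small motif", {
  truth <- random_truth_model(5, seed = 7, penalty_range = c(0.5, 2),
    consensus_margin = 3)
  train <- simulate_pbm(truth, n_probes = 1500, probe_length = 25,
    noise_sd = 0.2, seed = 10)
  heldout <- simulate_pbm(truth, n_probes = 600, probe_length = 25,
    noise_sd = 0.2, seed = 11)
  fit <- fit_binding_model(train, motif_length = 5, n_restarts = 2, seed = 1,
    max_epochs = 800)
  al <- align_energy_matrices(fit$models[[1]]$energy, truth$energy)
  expect_gt(al$r, 0.85)
  expect_gt(
    cor(predict_intensities(fit$models[[1]], heldout), heldout$signal),
    0.8
  )
})

test_that("model selection maximizes held-out correlation with tie rules", {
  truth <- random_truth_model(5, seed = 7, penalty_range = c(0.5, 2),
    consensus_margin = 3)
  heldout <- simulate_pbm(truth, n_probes = 500, probe_length = 25,
    noise_sd = 0.2, seed = 12)

  # wrap the generating model and a random model as one-model "fits"
  as_fit <- function(model, L) {
    structure(
      list(
        models = list(model), objective = 0, training_error = 0,
        hyper = list(hyper_params()), traces = list(0), seeds = 1,
        motif_length = L, dependent = FALSE, n = 0
      ),
      class = "pbem_fit"
    )
  }
  decoy <- random_truth_model(5, seed = 99)
  sel <- select_model(list(as_fit(truth, 5), as_fit(decoy, 5)), heldout)
  expect_identical(sel$model$energy, truth$energy)
  expect_gt(sel$correlation, 0.8)

  # single candidate comes back with its correlation
  sel1 <- select_model(as_fit(truth, 5), heldout)
  expect_equal(sel1$rank, 1)
  expect_equal(sel1$correlation, sel$correlation)

  # identical correlations: the smaller motif length wins
  sel2 <- select_model(list(as_fit(truth, 7), as_fit(truth, 5)), heldout)
  expect_equal(sel2$motif_length, 5)

  expect_error(select_model(as_fit(truth, 5), heldout[0, ]),
    class = "pbem_empty_input_error"
  )
})

test_that("alignment finds planted shifts and strand flips", {
  truth <- random_truth_model(8, seed = 15)
  E <- truth$energy
  self <- align_energy_matrices(E, E)
  expect_equal(self$r, 1)
  expect_equal(self$shift, 0)
  expect_equal(self$strand, "+")

  rc <- E[8:1, 4:1]
  flip <- align_energy_matrices(E, rc)
  expect_equal(flip$r, 1)
  expect_equal(flip$strand, "-")

  shifted <- rbind(E[3:8, ], matrix(0, 2, 4))
  sh <- align_energy_matrices(E, shifted)
  expect_equal(sh$r, 1, tolerance = 1e-10)
  expect_equal(abs(sh$shift), 2)
})

test_that("the motif-length scan picks the planted length", {
  truth <- random_truth_model(5, seed = 7, penalty_range = c(0.5, 2),
    consensus_margin = 3)
  train <- simulate_pbm(truth, n_probes = 600, probe_length = 22,
    noise_sd = 0.2, seed = 14)
  heldout <- simulate_pbm(truth, n_probes = 300, probe_length = 22,
    noise_sd = 0.2, seed = 15)
  sel <- scan_motif_lengths(train, heldout,
    motif_lengths = 4:6,
    n_restarts = 1, seed = 1, max_epochs = 400
  )
  expect_length(sel$fits, 3)
  expect_equal(nrow(sel$candidates), sum(lengths(lapply(sel$fits, `[[`, "models"))))
  expect_gt(sel$correlation, 0.6)
  # the winner should be at or adjacent to the generating length
  expect_true(abs(sel$motif_length - 5) <= 1)
})
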