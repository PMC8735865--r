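test_that("percent-of-optimal is the stated affine rescaling", {
  expect_equal(percent_optimal(-100, -100, -200), 100)
  expect_equal(percent_optimal(-200, -100, -200), 0)
  expect_equal(percent_optimal(-150, -100, -200), 50)
  # affine invariance under a common shift
  expect_equal(percent_optimal(-150 + 7, -100 + 7, -200 + 7), 50)
  expect_error(percent_optimal(-1, -5, -2), "reference")
})

test_that("effective learning rate implements the update/error ratio", {
  # p = 0.5, x = 1, p' = 0.6 -> alpha = 0.2 (the update upon the second
  # observation moves the prediction from 0.5 to 0.6)
  lr <- effective_learning_rate(c(0.5, 0.5, 0.6), c(1L, 1L))
  expect_equal(lr$alpha[2L], 0.2)
  # first step is referenced to 0.5: alpha_0 = (p_0 - 0.5) / (x_0 - 0.5)
  expect_equal(lr$alpha[1L], 0)
  # a vanishing prediction error masks the step
  lr <- effective_learning_rate(c(0.5, 1 - 1e-9, 0.4), c(1L, 1L))
  expect_false(lr$valid[2L])
  expect_true(is.na(lr$alpha[2L]))
  expect_error(effective_learning_rate(c(0.5, 0.6), c(1L, 0L)), "length")
})

test_that("readout recovers linear targets and rejects noise", {
  set.seed(42)
  H <- matrix(rnorm(12000 * 11), ncol = 11)
  w <- rnorm(11)
  y <- as.numeric(H %*% w) + 2.5
  i_tr <- 1:9000
  ro <- fit_readout(H[i_tr, ], y[i_tr], label = "exact")
  expect_equal(evaluate_readout(ro, H[-i_tr, ], y[-i_tr]), 1,
               tolerance = 1e-10)
  expect_equal(ro$weights, w, tolerance = 1e-8)
  # sign-flipped readout anti-correlates perfectly
  flip <- ro; flip$weights <- -flip$weights; flip$intercept <- -flip$intercept
  expect_equal(evaluate_readout(flip, H[-i_tr, ], y[-i_tr]), -1,
               tolerance = 1e-10)
  # pure-noise target: held-out r near zero at 38,000 test samples
  H2 <- matrix(rnorm(48000 * 11), ncol = 11)
  y2 <- rnorm(48000)
  ro2 <- fit_readout(H2[1:10000, ], y2[1:10000])
  expect_lt(abs(evaluate_readout(ro2, H2[10001:48000, ], y2[10001:48000])),
            0.05)
  # rank deficiency is flagged
  H3 <- cbind(H[1:100, 1:3], H[1:100, 3])
  expect_warning(fit_readout(H3, rnorm(100)), "rank")
  expect_error(evaluate_readout(ro, H[1:5, ] * 0, rep(1, 5)), "zero-variance")
})

test_that("mutual information behaves like a binned plug-in estimator", {
  set.seed(7)
  a <- runif(3200)
  expect_equal(mutual_information(a, a, bins = 32), log(32),
               tolerance = 1e-10)
  b <- runif(50000); a2 <- runif(50000)
  expect_lt(mutual_information(a2, b, bins = 32), 3 * 31^2 / (2 * 50000))
  expect_warning(mi0 <- mutual_information(rep(1, 100), runif(100)),
                 "constant")
  expect_equal(mi0, 0)
})

test_that("subspace projection orthogonalises by Gram-Schmidt", {
  w_pred <- c(1, 0, 0, 0, 0)
  w_prec <- c(0, 2, 0, 0, 0)
  # orthogonal axes: precision axis is left unchanged (normalised)
  xy <- project_subspace(c(3, 4, 0, 0, 0), w_pred, w_prec)
  expect_equal(as.numeric(xy), c(3, 4))
  # a state equal to the prediction vector has zero precision coordinate
  xy <- project_subspace(w_pred, w_pred, c(1, 1, 0, 0, 0))
  expect_equal(unname(xy[1, "prec"]), 0, tolerance = 1e-12)
  # states in the span are reconstructed exactly
  set.seed(1)
  wp <- rnorm(8); wq <- rnorm(8)
  state <- 0.7 * wp + 1.3 * wq
  xy <- project_subspace(state, wp, wq)
  u1 <- wp / sqrt(sum(wp^2))
  v <- wq - sum(wq * u1) * u1; u2 <- v / sqrt(sum(v^2))
  expect_lt(max(abs(xy[1, 1] * u1 + xy[1, 2] * u2 - state)), 1e-10)
  expect_error(project_subspace(state, wp, 2 * wp), "collinear")
})

test_that("perturbation vectors satisfy all three constraints to 1e-10", {
  set.seed(99)
  for (i in 1:1000) {
    N <- sample(3:12, 1)
    wp <- rnorm(N); wq <- rnorm(N)
    cc <- runif(1, 0.5, 2)
    # keep delta feasible: |beta_psi| * ||q_psi|| <= c
    u1 <- wp / sqrt(sum(wp^2))
    qpsi <- wq - sum(wq * u1) * u1
    dmax <- cc * sum(qpsi * wq) / sqrt(sum(qpsi^2))
    delta <- runif(1, -0.9, 0.9) * dmax
    q <- make_perturbation(wp, wq, delta, cc)
    expect_lt(abs(sum(q * wp)), 1e-10)
    expect_lt(abs(sum(q * wq) - delta), 1e-10)
    expect_lt(abs(sqrt(sum(q^2)) - cc), 1e-10)
  }
})

test_that("perturbations agree with the constrained minimum-norm solution", {
  # oracle: the minimum-norm vector satisfying the two linear constraints,
  # from the normal equations; any valid q is that solution plus a
  # component orthogonal to both constraint vectors
  set.seed(5)
  wp <- rnorm(9); wq <- rnorm(9)
  A <- rbind(wp, wq); b <- c(0, 0.4)
  q0 <- as.numeric(t(A) %*% solve(A %*% t(A), b))
  cmin <- sqrt(sum(q0^2))
  q <- make_perturbation(wp, wq, 0.4, cmin * 1.5)
  resid <- q - q0
  expect_lt(abs(sum(resid * wp)), 1e-10)
  expect_lt(abs(sum(resid * wq)), 1e-10)
  # below the minimum-norm intensity the constraints are infeasible
  expect_error(make_perturbation(wp, wq, 0.4, cmin * 0.9), "infeasible")
  expect_error(make_perturbation(wp, 3 * wp, 0.1, 1), "degenerate")
  # zero intensity with zero delta is the null perturbation
  expect_equal(make_perturbation(wp, wq, 0, 0), rep(0, 9))
})

test_that("a null perturbation leaves the learning rate unchanged", {
  net <- gated_unigram_nets()[[1L]]
  ro <- precision_readouts()[[1L]]
  seqs <- unigram_ro_test()[1:10]
  pe <- perturbation_experiment(net, ro, seqs, deltas = 0,
                                intensity = 1e-14, n_probes = 50, seed = 2)
  expect_lt(max(abs(pe$changes)), 1e-6)
})

test_that("power-law fits recover planted parameters", {
  N <- c(2, 3, 5, 8, 12, 20, 33, 45)
  p <- 100 - 40 * (1 / N)^0.7
  fit <- fit_power_law(N, p)
  expect_equal(fit$coefficient, 40, tolerance = 1e-10)
  expect_equal(fit$exponent, 0.7, tolerance = 1e-10)
  expect_equal(fit$r_squared, 100, tolerance = 1e-8)
  expect_equal(predict(fit, N), p, tolerance = 1e-8)
  # 1% multiplicative noise, 12 sizes: exponent within 10%
  set.seed(3)
  N12 <- round(exp(seq(log(2), log(45), length.out = 12)))
  p12 <- 100 - 30 * (1 / N12)^0.6 * exp(rnorm(12, 0, 0.01))
  expect_lt(abs(fit_power_law(N12, p12)$exponent - 0.6) / 0.6, 0.1)
  expect_error(fit_power_law(c(2, 5), c(95, 100)), "below 100")
})

test_that("group statistics match hand-computed references", {
  a <- c(1.2, 2.1, 3.3, 4.0, 5.2)
  b <- c(2.0, 3.1, 4.2, 5.5, 6.1, 7.0)
  res <- group_statistics(a, b, "welch_two_sided")
  # Welch formula computed directly
  se <- sqrt(var(a) / 5 + var(b) / 6)
  tref <- (mean(a) - mean(b)) / se
  dfref <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 6)^2 / 5)
  expect_equal(res$statistic, tref, tolerance = 1e-10)
  expect_equal(res$df, dfref, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(tref, dfref), tolerance = 1e-10)
  # identical samples: t = 0, p = 1
  res0 <- group_statistics(a, a, "welch_two_sided")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # constant paired difference is flagged degenerate
  expect_warning(resd <- group_statistics(b[1:5] + 1, b[1:5],
                                          "paired_one_sided"), "degenerate")
  expect_true(resd$degenerate)
  expect_equal(resd$p_value, 0)
  # interaction F against the balanced two-way closed form
  cells <- list(c(1, 2, 3), c(2, 3, 4), c(1.5, 2.5, 3.5), c(6, 7, 8))
  resf <- group_statistics(cells[1:2], cells[3:4], "interaction_f")
  y <- unlist(cells)
  f1 <- factor(rep(c(0, 0, 1, 1), each = 3))
  f2 <- factor(rep(c(0, 1, 0, 1), each = 3))
  m <- tapply(y, list(f1, f2), mean)
  ss_int <- 3 * (m[1, 1] - m[1, 2] - m[2, 1] + m[2, 2])^2 / 4
  sse <- sum((y - ave(y, f1, f2))^2)
  fref <- (ss_int / 1) / (sse / 8)
  expect_equal(resf$statistic, fref, tolerance = 1e-10)
})

test_that("optimal streak-transfer reference separates the two couplings", {
  probes <- generate_streak_probes(31, n_per_condition = 15L,
                                   streak_range = c(2L, 5L, 10L, 20L, 40L))
  oc <- streak_probe_curve(optimal_agent("bigram_coupled"), probes)
  oi <- streak_probe_curve(optimal_agent("bigram_independent"), probes)
  expect_gt(mean(oc), mean(oi))
  # under coupling, long surprising streaks transfer more suspicion
  expect_gt(oc[["40"]], oc[["2"]])
  # a unigram delta rule provides a structure-blind baseline
  base <- streak_probe_curve(heuristic_agent("delta", "unigram", 0.1), probes)
  expect_true(all(base >= 0 & base <= 1))
})
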