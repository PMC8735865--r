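test_that("transition kernel has the correct limits and factorisation", {
  for (st in c("unigram", "bigram_independent", "bigram_coupled")) {
    agent0 <- optimal_agent(st, change_prob = 0)
    agent1 <- optimal_agent(st, change_prob = 1)
    state <- posterior_init(agent0)
    # put some non-uniform mass in
    state <- posterior_update(agent0, state, 1L)
    expect_equal(posterior_transition(agent0, state)$mass, state$mass,
                 tolerance = 1e-14)
    u <- posterior_init(agent1)$mass
    expect_equal(posterior_transition(agent1, state)$mass, u,
                 tolerance = 1e-14)
  }

  # independent kernel on a point mass equals the tensor product of the
  # 1-D transitioned marginals, and matches a dense 400x400 kernel product
  pc <- 0.3
  agent <- optimal_agent("bigram_independent", pc)
  n <- agent$n_bins
  m <- matrix(0, n, n); m[4L, 17L] <- 1
  out <- posterior_transition(agent, list(mass = m, prev_obs = 0L))$mass
  k1 <- rep(pc / n, n); k1[4L] <- k1[4L] + (1 - pc)
  k2 <- rep(pc / n, n); k2[17L] <- k2[17L] + (1 - pc)
  expect_equal(out, outer(k1, k2), tolerance = 1e-14)
  K <- (1 - pc) * diag(n) + pc / n
  K_joint <- kronecker(K, K)   # column-major vectorisation oracle
  expect_equal(as.numeric(out), as.numeric(K_joint %*% as.numeric(m)),
               tolerance = 1e-13)
})

test_that("Bayes update matches direct grid sums and factorises correctly", {
  agent <- optimal_agent("unigram")
  v <- agent$bin_values
  st <- posterior_update(agent, posterior_init(agent), 1L)
  expect_equal(st$mass, v / sum(v), tolerance = 1e-14)
  s <- posterior_summary(agent, st)
  expect_equal(s$mean[1L], sum(v^2) / sum(v), tolerance = 1e-14)

  # likelihood products commute
  a <- posterior_update(agent, posterior_update(agent,
                                                posterior_init(agent), 1L), 0L)
  b <- posterior_update(agent, posterior_update(agent,
                                                posterior_init(agent), 0L), 1L)
  expect_equal(a$mass, b$mass, tolerance = 1e-14)

  # bigram: obs 0 after prev 0 touches only the p(0|0) dimension
  bagent <- optimal_agent("bigram_independent")
  st <- posterior_update(bagent, posterior_init(bagent), 0L)
  expect_equal(rowSums(st$mass), v / sum(v), tolerance = 1e-14)
  expect_equal(colSums(st$mass), rep(1 / 20, 20), tolerance = 1e-14)
})

test_that("summaries of canonical posteriors are exact", {
  agent <- optimal_agent("unigram")
  v <- agent$bin_values
  s <- posterior_summary(agent, posterior_init(agent))
  expect_equal(s$prediction, 0.5)
  expect_equal(s$sd[1L], sqrt(mean(v^2) - 0.25), tolerance = 1e-14)
  # near-point mass: prediction approaches the bin value; exact point mass
  # has zero SD and must signal
  m <- rep(1e-12, 20); m[7L] <- 1 - 19e-12
  s <- posterior_summary(agent, list(mass = m, prev_obs = 0L))
  expect_equal(s$prediction, v[7L], tolerance = 1e-9)
  m0 <- rep(0, 20); m0[7L] <- 1
  expect_error(posterior_summary(agent, list(mass = m0, prev_obs = 0L)),
               "degenerate")
  # bigram uniform prior, prev_obs = 1: prediction 0.5 by symmetry
  bagent <- optimal_agent("bigram_coupled")
  st <- posterior_init(bagent); st$prev_obs <- 1L
  expect_equal(posterior_summary(bagent, st)$prediction, 0.5)
})

test_that("the first emitted prediction is 0.5 in every environment", {
  for (st in c("unigram", "bigram_independent", "bigram_coupled")) {
    agent <- optimal_agent(st)
    s <- generate_sequence(env_config(st, length = 30), 4)
    expect_equal(predict(agent, s)$predictions[1L], 0.5)
  }
})

test_that("static posterior mean approaches the Beta-Laplace rule", {
  agent <- optimal_agent("unigram", change_prob = 0)
  x <- c(rep(1L, 5), rep(0L, 3))
  tr <- predict(agent, x)
  # grid-sum oracle for the same quantity
  v <- agent$bin_values
  lik <- v^5 * (1 - v)^3
  expect_equal(unname(tr$post_mean[9L, 1L]), sum(lik * v) / sum(lik),
               tolerance = 1e-12)
  expect_lt(abs(tr$post_mean[9L, 1L] - 6 / 10), 0.01)  # (n+1)/(n+m+2)
})

test_that("forward filter matches the brute-force enumeration oracle", {
  pc <- 0.2
  x7 <- c(1L, 1L, 0L, 1L, 0L, 0L, 1L)
  agent <- optimal_agent("unigram", pc)
  tr <- predict(agent, x7)
  for (k in 0:6) {
    expect_equal(tr$predictions[k + 1L], enum_predict_unigram(x7, k, pc),
                 tolerance = 1e-10)
  }
  x6 <- c(0L, 1L, 1L, 0L, 1L, 1L)
  for (st in c("bigram_independent", "bigram_coupled")) {
    agent <- optimal_agent(st, pc)
    tr <- predict(agent, x6)
    for (k in 0:5) {
      expect_equal(tr$predictions[k + 1L],
                   enum_predict_bigram(x6, k, pc, st == "bigram_coupled"),
                   tolerance = 1e-10)
    }
  }
})

test_that("posterior mass stays normalised along whole sequences", {
  for (st in c("unigram", "bigram_independent", "bigram_coupled")) {
    agent <- optimal_agent(st)
    s <- generate_sequence(env_config(st, length = 120), 9)
    state <- posterior_init(agent)
    for (k in seq_along(s$x)) {
      state <- posterior_transition(agent,
                                    posterior_update(agent, state, s$x[k]))
      expect_lt(abs(sum(state$mass) - 1), 1e-12)
      expect_true(all(state$mass >= 0))
    }
  }
})

test_that("precision grows on consistent evidence and drops at surprises", {
  # without change points, a run of identical observations sharpens the
  # posterior monotonically
  agent0 <- optimal_agent("unigram", change_prob = 0)
  tr <- predict(agent0, rep(1L, 30))
  psi <- tr$psi[, 1L]
  expect_true(all(diff(psi) > 0))
  # with a change-point hazard, a lone contradiction after a long run
  # lowers the precision
  agent <- optimal_agent("unigram", 1 / 75)
  tr <- predict(agent, c(rep(1L, 40), 0L))
  psi <- tr$psi[, 1L]
  expect_lt(psi[42L], psi[41L])
})

test_that("posterior trace is shaped and typed as documented", {
  s <- generate_sequence(env_config("bigram_independent", length = 60), 2)
  tr <- predict(optimal_agent("bigram_independent"), s)
  expect_length(tr$predictions, 61L)
  expect_identical(dim(tr$psi), c(61L, 2L))
  expect_true(all(tr$predictions > 0 & tr$predictions < 1))
  expect_true(all(is.finite(tr$psi)))
  expect_true(all(tr$post_sd > 0))
})
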