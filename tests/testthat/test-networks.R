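test_that("hyperparameter lookup returns the tabulated rows", {
  hp <- load_hyperparameters("unigram", "gated", 11)
  expect_equal(hp$eta0, 6.60e-2)
  expect_equal(hp$sigma0_x, 0.43)
  expect_equal(hp$sigma0_h, 0.21)
  expect_equal(hp$mu0_h_ii, 0)
  expect_equal(load_hyperparameters("bigram", "no_lateral", 11)$mu0_h_ii, 0)
  expect_equal(load_hyperparameters("unigram", "no_lateral", 11)$mu0_h_ii, 1)
  # nearest size in log space: 30 is closer to 45 than to 11
  expect_equal(load_hyperparameters("unigram", "gated", 30)$n_units, 45)
  expect_error(load_hyperparameters("unigram", "gated", 30, fallback = FALSE),
               "fallback")
  expect_equal(load_hyperparameters("bigram_coupled", "gated", 11)$eta0,
               4.40e-2)
})

test_that("initialisation respects the stated distributions and structure", {
  net <- init_rnn("gated", "unigram", n_units = 11, seed = 5)
  p <- net$params
  for (b in c("bxr", "bhr", "bxz", "bhz", "bxh", "bhh")) {
    expect_true(all(abs(p[[b]]) <= 1 / 11))
  }
  expect_true(abs(p$bhp) <= 1 / 11)
  nl <- init_rnn("no_lateral", "unigram", n_units = 11, seed = 5)
  off <- row(nl$params$Whh) != col(nl$params$Whh)
  expect_true(all(nl$params$Whh[off] == 0))
  expect_true(all(nl$params$Whr[off] == 0))
  ng <- init_rnn("no_gating", "unigram", n_units = 11, seed = 5)
  expect_null(ng$params$Wxr)
  # output-weight SD: pool draws over many initialisations
  w <- unlist(lapply(1:1000, function(s)
    init_rnn("gated", "unigram", n_units = 11, seed = s)$params$whp))
  expect_lt(abs(sd(w) - 1 / 11) / (1 / 11), 0.05)
})

test_that("single-step dynamics have the documented fixed points and gates", {
  N <- 4L
  zero <- init_rnn("gated", "unigram", n_units = N, seed = 1)
  for (nm in setdiff(names(zero$params), c("arch", "n_units"))) {
    zero$params[[nm]][] <- 0
  }
  expect_equal(network_step(zero, rep(0, N), 0L), rep(0, N))
  expect_equal(network_output(zero, rep(0, N)), 0.5)
  # saturated update gate freezes the state
  frozen <- zero
  frozen$params$bxz[] <- 40
  h <- c(0.3, -0.2, 0.1, 0.5)
  expect_equal(network_step(frozen, h, 1L), h, tolerance = 1e-12)
  # large output bias saturates the sigmoid
  big <- zero; big$params$bhp <- 10
  expect_equal(network_output(big, rep(0, N)), plogis(10))
  # output ignores components with zero output weight
  mixed <- zero; mixed$params$whp <- c(1, 0, 0, 0)
  expect_equal(network_output(mixed, c(0.2, 9, -9, 3)),
               network_output(mixed, c(0.2, 0, 0, 0)))
})

test_that("hidden states stay inside (-1, 1) for all architectures", {
  for (arch in c("gated", "no_gating", "no_lateral", "frozen_recurrence")) {
    for (draw in 1:25) {
      net <- init_rnn(arch, "bigram", n_units = 6,
                      seed = 1000L + draw)
      # inflate weights to stress the bound
      net$params$Whh <- net$params$Whh * 5
      h <- rep(0, 6)
      x <- rep(c(1L, 0L, 1L), length.out = 50)
      for (t in 1:50) {
        h <- network_step(net, h, x[t])
        expect_true(all(abs(h) < 1))
      }
    }
  }
})

test_that("gated dynamics nest the ungated ones when the gates saturate", {
  g <- init_rnn("gated", "unigram", n_units = 5, seed = 2)
  ng <- init_rnn("no_gating", "unigram", n_units = 5, seed = 3)
  # share the candidate-path weights; clamp r -> 1, z -> 0
  for (nm in c("Wxh", "bxh", "Whh", "bhh", "whp", "bhp")) {
    g$params[[nm]] <- ng$params[[nm]]
  }
  g$params$Wxr[] <- 0; g$params$Whr[] <- 0
  g$params$bxr[] <- 40; g$params$bhr[] <- 0
  g$params$Wxz[] <- 0; g$params$Whz[] <- 0
  g$params$bxz[] <- -40; g$params$bhz[] <- 0
  h <- rep(0, 5)
  for (x in c(1L, 0L, 0L, 1L, 1L)) {
    expect_equal(network_step(g, h, x), network_step(ng, h, x),
                 tolerance = 1e-12)
    h <- network_step(ng, h, x)
  }
})

test_that("R single-step dynamics agree with the compiled forward pass", {
  for (arch in c("gated", "no_gating", "no_lateral")) {
    net <- init_rnn(arch, "bigram", n_units = 7, seed = 11)
    x <- generate_sequence(env_config("unigram", length = 40), 3)$x
    tr <- predict(net, x)
    h <- rep(0, 7)
    preds <- network_output(net, h)
    for (t in seq_along(x)) {
      h <- network_step(net, h, x[t])
      preds <- c(preds, network_output(net, h))
      expect_equal(unname(tr$hidden[t, ]), h, tolerance = 1e-12)
    }
    expect_equal(tr$predictions, preds, tolerance = 1e-12)
  }
})

test_that("network traces are shaped as documented; zero net is chance", {
  net <- init_rnn("gated", "unigram", n_units = 11, seed = 1)
  for (nm in setdiff(names(net$params), c("arch", "n_units"))) {
    net$params[[nm]][] <- 0
  }
  x <- generate_sequence(env_config("unigram", length = 80), 5)$x
  tr <- predict(net, x)
  expect_length(tr$predictions, 81L)
  expect_identical(dim(tr$hidden), c(80L, 11L))
  expect_equal(tr$predictions, rep(0.5, 81))
  expect_equal(tr$log_lik, -79 * log(2))
})

test_that("BPTT gradients match central finite differences", {
  x <- matrix(c(1L, 0L, 1L, 1L, 0L), nrow = 1)
  for (arch in c("gated", "no_gating")) {
    net <- init_rnn(arch, "unigram", n_units = 3, seed = 7)
    ana <- seqvol:::cpp_loss_grad(net$params, x)$gradients
    num <- numeric_net_grad(net$params, x)
    for (nm in names(num)) {
      expect_lt(max(abs(ana[[nm]] - num[[nm]]) /
                      pmax(1e-6, abs(num[[nm]]))), 1e-5)
    }
  }
})

test_that("training respects the architecture masks and is deterministic", {
  tiny <- generate_dataset(env_config("unigram", length = 60), 40, seed = 3)
  fr <- fit_rnn("frozen_recurrence", tiny, n_units = 5, seed = 4)
  for (nm in setdiff(names(fr$params), c("arch", "n_units", "whp", "bhp"))) {
    expect_identical(fr$params[[nm]], fr$init_params[[nm]])
  }
  expect_false(identical(fr$params$whp, fr$init_params$whp))

  nl <- fit_rnn("no_lateral", tiny, n_units = 5, seed = 4)
  off <- row(nl$params$Whh) != col(nl$params$Whh)
  expect_true(all(nl$params$Whh[off] == 0))
  expect_true(all(nl$params$Whz[off] == 0))
  expect_false(all(diag(nl$params$Whh) == diag(nl$init_params$Whh)))

  a <- fit_rnn("gated", tiny, n_units = 5, seed = 9)
  b <- fit_rnn("gated", tiny, n_units = 5, seed = 9)
  expect_identical(a$params, b$params)
  expect_identical(predict(a, tiny[[1L]]), predict(b, tiny[[1L]]))
})

test_that("trained gated networks end below the chance loss", {
  for (net in gated_unigram_nets()) {
    expect_lt(net$loss[length(net$loss)], log(2))
  }
})
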