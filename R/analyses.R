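#' Percent-of-optimal log likelihood
#'
#' Affine rescaling of an agent's sequence log likelihood L so that chance
#' performance (constant prediction 0.5) maps to 0 and the ideal observer
#' maps to 100: \code{(L - L_chance) / (L_optimal - L_chance) * 100}.
#'
#' @param L agent log likelihood(s) (vectorised).
#' @param L_optimal ideal-observer log likelihood on the same data.
#' @param L_chance chance log likelihood on the same data.
#' @return numeric percentage(s).
#' @export
percent_optimal <- function(L, L_optimal, L_chance) {
  if (!(L_optimal > L_chance)) {
    stop("invalid reference: L_optimal must exceed L_chance")
  }
  (L - L_chance) / (L_optimal - L_chance) * 100
}

#' Total log likelihood of an agent over a set of sequences
#'
#' @param agent any agent with a \code{predict} method returning a trace
#'   with \code{log_lik} (optimal, heuristic or network agent).
#' @param sequences list of sequences.
#' @return scalar sum of per-sequence log likelihoods.
#' @export
agent_log_lik <- function(agent, sequences) {
  sum(vapply(sequences, function(s) predict(agent, s)$log_lik, numeric(1)))
}

#' Chance log likelihood for a set of sequences
#'
#' A constant prediction of 0.5 scores \code{-log 2} on each of the T-1
#' scored observations of a length-T sequence.
#'
#' @param sequences list of sequences (or binary vectors).
#' @return scalar log likelihood.
#' @export
chance_log_lik <- function(sequences) {
  -log(2) * sum(vapply(sequences,
                       function(s) length(observation_vector(s)) - 1L,
                       numeric(1)))
}

#' Group performance report
#'
#' @param L vector of per-agent log likelihoods.
#' @param L_optimal,L_chance reference log likelihoods.
#' @param conf confidence level for the Student-t interval over agents.
#' @return list with per-agent \code{percent}, group \code{mean},
#'   \code{ci} half-width, and the references.
#' @export
performance_report <- function(L, L_optimal, L_chance, conf = 0.95) {
  pct <- percent_optimal(L, L_optimal, L_chance)
  n <- length(pct)
  half <- if (n > 1L) stats::qt(1 - (1 - conf) / 2, n - 1L) *
    stats::sd(pct) / sqrt(n) else NA_real_
  structure(list(percent = pct, mean = mean(pct), ci = half,
                 L_optimal = L_optimal, L_chance = L_chance),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Performance (% of optimal log likelihood):\n")
  cat("  mean ", format(x$mean, digits = 4),
      if (!is.na(x$ci)) paste0(" (CI half-width ", format(x$ci, digits = 3), ")"),
      ", n = ", length(x$percent), "\n", sep = "")
  invisible(x)
}

#' Moment-by-moment effective learning rate
#'
#' The effective learning rate normalises each prediction update by the
#' preceding prediction error:
#' \deqn{\alpha_{t+1} = (p_{t+1} - p_t) / (x_{t+1} - p_t)}
#' with the very first update referenced to the neutral prediction 0.5.
#' Steps where the prediction error magnitude falls below \code{tol} are
#' flagged invalid and must be excluded from averages.
#'
#' @param predictions prediction vector of length T+1 (the package trace
#'   convention) or an \code{"agent_trace"} / \code{"posterior_trace"}.
#' @param observations binary vector of length T (unneeded when a trace
#'   from a \code{"seqvol_seq"} prediction is passed together with the
#'   sequence; always required otherwise).
#' @param tol degeneracy threshold on |x - p| (default 1e-6).
#' @return list of class \code{"learning_rate_trace"} with \code{alpha}
#'   (length T) and logical \code{valid}.
#' @export
effective_learning_rate <- function(predictions, observations, tol = 1e-6) {
  if (is.list(predictions)) predictions <- predictions$predictions
  x <- observation_vector(observations)
  T_ <- length(x)
  if (length(predictions) != T_ + 1L) {
    stop("predictions must have length T+1 for T observations")
  }
  ref <- c(0.5, predictions[2:T_])
  num <- predictions[2:(T_ + 1L)] - ref
  den <- x - ref
  valid <- abs(den) >= tol
  alpha <- ifelse(valid, num / den, NA_real_)
  structure(list(alpha = alpha, valid = valid),
            class = "learning_rate_trace")
}

#' Pairing of precision with the subsequent effective learning rate
#'
#' Correlates a precision series (one value per consumed observation, i.e.
#' \eqn{\psi} computed from the information available after observation t)
#' with the effective learning rate at the next step (the update performed
#' upon receiving observation t+1), pooling valid steps.
#'
#' @param psi numeric vector of length T (precision after each
#'   observation).
#' @param lr_trace a \code{"learning_rate_trace"} for the same sequence.
#' @return data frame with columns \code{psi} and \code{alpha_next}
#'   (invalid steps dropped), suitable for pooling before correlation.
#' @export
precision_learning_rate_pairs <- function(psi, lr_trace) {
  T_ <- length(lr_trace$alpha)
  stopifnot(length(psi) == T_)
  i <- seq_len(T_ - 1L)
  ok <- lr_trace$valid[i + 1L]
  data.frame(psi = psi[i][ok], alpha_next = lr_trace$alpha[i + 1L][ok])
}

#' Log precision of a posterior trace aligned with consumed observations
#'
#' Returns \eqn{\psi_t} for t = 1..T where entry t conditions on the first
#' t observations (the alignment used for readout targets: the network's
#' hidden state after observation t carries the same information set).
#'
#' @param trace a \code{"posterior_trace"}.
#' @param latent latent index (1 for the unigram variable or p(0|0); 2 for
#'   p(1|1)).
#' @return numeric vector of length T.
#' @export
trace_psi_steps <- function(trace, latent = 1L) {
  n <- nrow(trace$psi)
  trace$psi[2:n, latent]
}

#' @rdname trace_psi_steps
#' @export
trace_logodds_steps <- function(trace, latent = 1L) {
  n <- nrow(trace$post_mean)
  m <- trace$post_mean[2:n, latent]
  log(m / (1 - m))
}

#' Linear readout from recurrent activity
#'
#' Ordinary least squares (with intercept) from hidden-unit activations to
#' a target quantity, the standard linear-decoding model. If the design is
#' rank deficient the minimum-norm (pseudo-inverse) solution is returned
#' with a warning.
#'
#' @param hidden numeric matrix (samples x units), typically time steps
#'   pooled over sequences.
#' @param targets numeric target vector.
#' @param label optional target label.
#' @return object of class \code{"readout"}: \code{weights},
#'   \code{intercept}, \code{train_r} (Pearson r on the fitting data),
#'   \code{rank_deficient} flag.
#' @export
fit_readout <- function(hidden, targets, label = NULL) {
  hidden <- as.matrix(hidden)
  stopifnot(nrow(hidden) == length(targets))
  X <- cbind(1, hidden)
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    warning("rank-deficient design; returning pseudo-inverse solution")
    sv <- svd(X)
    keep <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], targets)) / sv$d[keep])
    beta <- as.numeric(beta)
  } else {
    beta <- qr.coef(qr_, targets)
  }
  fitted <- as.numeric(X %*% beta)
  structure(list(weights = unname(beta[-1L]), intercept = unname(beta[1L]),
                 train_r = stats::cor(fitted, targets),
                 rank_deficient = qr_$rank < ncol(X),
                 label = label),
            class = "readout")
}

#' @export
print.readout <- function(x, ...) {
  cat("<linear readout>", if (!is.null(x$label)) paste0(" of ", x$label),
      ": ", length(x$weights), " weights, train r = ",
      format(x$train_r, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_readout
#' @param readout a fitted \code{"readout"}.
#' @export
read_values <- function(readout, hidden) {
  as.numeric(as.matrix(hidden) %*% readout$weights) + readout$intercept
}

#' @rdname fit_readout
#' @description \code{evaluate_readout} computes the Pearson correlation
#'   between the read value and the target on held-out data.
#' @export
evaluate_readout <- function(readout, hidden, targets) {
  v <- read_values(readout, hidden)
  if (stats::sd(v) == 0 || stats::sd(targets) == 0) {
    stop("undefined correlation: zero-variance series")
  }
  stats::cor(v, targets)
}

#' Mutual information by equal-frequency binning
#'
#' Plug-in estimate of the mutual information (in nats) between two
#' continuous series after discretising each into \code{bins}
#' equal-frequency bins. The estimator is biased upward by at most about
#' \code{(bins-1)^2 / (2n)} nats for independent series.
#'
#' @param a,b equal-length numeric vectors.
#' @param bins number of bins per series (default 32).
#' @return nonnegative scalar, nats.
#' @export
mutual_information <- function(a, b, bins = 32L) {
  stopifnot(length(a) == length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant series: mutual information is 0")
    return(0)
  }
  cut_ef <- function(v) {
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1L)))
    if (length(br) < 3L) br <- c(-Inf, stats::median(v), Inf)
    findInterval(v, br[-c(1L, length(br))]) + 1L
  }
  ja <- cut_ef(a); jb <- cut_ef(b)
  tab <- table(ja, jb) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  nz <- tab > 0
  sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
}

#' Projection onto the prediction-precision subspace
#'
#' Projects hidden states onto the plane spanned by the output (prediction)
#' weight vector and the precision-readout weight vector, with the
#' precision axis orthogonalised against the prediction axis by
#' Gram-Schmidt.
#'
#' @param hidden samples x units matrix (or a single state vector).
#' @param w_pred output weight vector.
#' @param w_prec precision readout weight vector.
#' @return samples x 2 matrix of coordinates (columns: prediction axis,
#'   orthogonalised precision axis).
#' @export
project_subspace <- function(hidden, w_pred, w_prec) {
  if (is.null(dim(hidden))) hidden <- matrix(hidden, nrow = 1L)
  np <- sqrt(sum(w_pred^2)); nq <- sqrt(sum(w_prec^2))
  if (np == 0 || nq == 0) stop("zero axis vector")
  u1 <- w_pred / np
  v <- w_prec - sum(w_prec * u1) * u1
  if (sqrt(sum(v^2)) < 1e-12 * nq) {
    stop("degenerate subspace: prediction and precision vectors collinear")
  }
  u2 <- v / sqrt(sum(v^2))
  cbind(pred = as.numeric(hidden %*% u1), prec = as.numeric(hidden %*% u2))
}

#' Constrained random activity perturbation
#'
#' Generates a perturbation vector q of the recurrent state satisfying, to
#' numerical precision: no change in the network prediction
#' (\eqn{q \cdot w_{pred} = 0}), a controlled change \code{delta} in the
#' read precision (\eqn{q \cdot w_{prec} = \delta}), and constant intensity
#' (\eqn{\|q\| = c}). The construction projects the precision vector into
#' the null space of the prediction vector, scales it to produce
#' \code{delta}, and fills the remaining norm with a random unit vector
#' orthogonal to both axes.
#'
#' @param w_pred,w_prec prediction (output) and precision-readout weight
#'   vectors, length N >= 3, not collinear.
#' @param delta desired change in read precision.
#' @param c perturbation norm (> 0).
#' @return numeric perturbation vector of length N.
#' @export
make_perturbation <- function(w_pred, w_prec, delta, c) {
  N <- length(w_pred)
  stopifnot(length(w_prec) == N, N >= 3L, c >= 0)
  if (c == 0 && delta == 0) return(numeric(N))
  u1 <- w_pred / sqrt(sum(w_pred^2))
  q_psi <- w_prec - sum(w_prec * u1) * u1     # projection of w_prec onto Q
  nq2 <- sum(q_psi^2)
  if (nq2 < (1e-12 * sqrt(sum(w_prec^2)))^2) {
    stop("degenerate: prediction and precision vectors collinear")
  }
  beta_psi <- delta / sum(q_psi * w_prec)
  rem <- c^2 - beta_psi^2 * nq2
  if (rem < -1e-12 * c^2) {
    stop("infeasible perturbation: norm c too small for requested delta")
  }
  rem <- max(rem, 0)
  # orthonormal completion of span(w_pred, q_psi)
  B <- qr.Q(qr(cbind(u1, q_psi / sqrt(nq2))), complete = TRUE)[, -(1:2),
                                                               drop = FALSE]
  g <- stats::rnorm(N - 2L)
  q_r <- as.numeric(B %*% g)
  q_r <- q_r / sqrt(sum(q_r^2))
  beta_psi * q_psi + sqrt(rem) * q_r
}

#' Causal perturbation experiment on the read precision
#'
#' Tests whether the precision represented in a network's activity causally
#' regulates its effective learning rate. At randomly drawn probe time
#' points, the hidden state is displaced by a constrained random
#' perturbation (\code{\link{make_perturbation}}) that changes the read
#' precision by \code{delta} while leaving the current prediction (and
#' hence the next prediction error) untouched; the network is advanced one
#' step and the change in effective learning rate relative to the
#' unperturbed run is recorded.
#'
#' @param net a trained \code{"rnn_agent"}.
#' @param readout the fitted precision \code{"readout"} of this network.
#' @param sequences out-of-sample sequences to probe.
#' @param deltas precision-change levels; default: 5 equally spaced levels
#'   spanning plus/minus one SD of the read precision on these sequences.
#' @param intensity perturbation norm c; default 0.1 times the median
#'   hidden-state norm across probe points.
#' @param n_probes number of probe time points (default 1000).
#' @param seed integer seed (probe sampling and random perturbation
#'   components).
#' @param t_min earliest probe time step (default 10, skipping the initial
#'   transient).
#' @return object of class \code{"perturbation_result"}: \code{deltas},
#'   \code{intensity}, \code{mean_change} (per delta),
#'   \code{changes} (probes x deltas matrix).
#' @export
perturbation_experiment <- function(net, readout, sequences, deltas = NULL,
                                    intensity = NULL, n_probes = 1000L,
                                    seed = 1L, t_min = 10L) {
  traces <- lapply(sequences, function(s) predict(net, s))
  xs <- lapply(sequences, observation_vector)
  T_ <- length(xs[[1L]])
  with_seed(derive_seed(seed, 3L), {
    # candidate probe points: step i in [t_min, T-1] so a next step exists
    cand_seq <- sample.int(length(sequences), n_probes * 4L, replace = TRUE)
    cand_t <- sample(seq(t_min, T_ - 1L), n_probes * 4L, replace = TRUE)
    keep <- logical(length(cand_seq))
    for (j in seq_along(cand_seq)) {
      tr <- traces[[cand_seq[j]]]
      keep[j] <- abs(xs[[cand_seq[j]]][cand_t[j] + 1L] -
                       tr$predictions[cand_t[j] + 1L]) >= 1e-6
    }
    idx <- which(keep)
    if (length(idx) < n_probes) stop("not enough non-degenerate probe points")
    idx <- idx[seq_len(n_probes)]
    probe_seq <- cand_seq[idx]
    probe_t <- cand_t[idx]

    if (is.null(deltas) || is.null(intensity)) {
      psi_hat <- unlist(lapply(traces, function(tr)
        read_values(readout, tr$hidden)))
      if (is.null(deltas)) {
        s <- stats::sd(psi_hat)
        deltas <- seq(-s, s, length.out = 5L)
      }
      if (is.null(intensity)) {
        norms <- vapply(seq_len(n_probes), function(j)
          sqrt(sum(traces[[probe_seq[j]]]$hidden[probe_t[j], ]^2)),
          numeric(1))
        intensity <- 0.1 * stats::median(norms)
      }
    }

    w_pred <- net$params$whp
    changes <- matrix(NA_real_, n_probes, length(deltas))
    for (j in seq_len(n_probes)) {
      tr <- traces[[probe_seq[j]]]
      x <- xs[[probe_seq[j]]]
      i <- probe_t[j]
      h <- tr$hidden[i, ]
      p_now <- tr$predictions[i + 1L]
      x_next <- x[i + 1L]
      alpha0 <- (tr$predictions[i + 2L] - p_now) / (x_next - p_now)
      for (d in seq_along(deltas)) {
        q <- make_perturbation(w_pred, readout$weights, deltas[d], intensity)
        h2 <- network_step(net, h + q, x_next)
        p_next <- network_output(net, h2)
        changes[j, d] <- (p_next - p_now) / (x_next - p_now) - alpha0
      }
    }
    structure(list(deltas = deltas, intensity = intensity,
                   mean_change = colMeans(changes), changes = changes),
              class = "perturbation_result")
  })
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat("<perturbation experiment> c = ", format(x$intensity, digits = 4),
      ", ", nrow(x$changes), " probes\n", sep = "")
  print(data.frame(delta = x$deltas, mean_change = x$mean_change),
        row.names = FALSE)
  invisible(x)
}

#' Streak probe curve of an agent
#'
#' Runs an agent through each probe prefix, queries the prediction for the
#' unobserved bigram (feeding the query observation), presents m repeated
#' observations of the observed bigram, queries again, and averages
#' |p_after - p_before| over all probe sequences for each streak length m.
#' An agent that transfers the suspicion of a change from the observed to
#' the unobserved bigram shows a larger change than one that does not.
#'
#' @param agent an \code{"rnn_agent"}, \code{"optimal_agent"} or
#'   \code{"heuristic_agent"}.
#' @param probes a \code{\link{generate_streak_probes}} probe set.
#' @return named numeric vector: mean |p_after - p_before| per streak
#'   length.
#' @export
streak_probe_curve <- function(agent, probes) {
  UseMethod("streak_probe_curve")
}

#' @export
streak_probe_curve.rnn_agent <- function(agent, probes) {
  ms <- attr(probes, "streak_range")
  acc <- matrix(0, 0, length(ms))
  for (cond in probes) {
    X <- do.call(rbind, cond$sequences)
    storage.mode(X) <- "integer"
    res <- cpp_streak_probe(agent$params, X, cond$query_value,
                            cond$streak_value, as.integer(ms))
    acc <- rbind(acc, abs(res$p_after - res$p_before))
  }
  stats::setNames(colMeans(acc), ms)
}

#' @export
streak_probe_curve.optimal_agent <- function(agent, probes) {
  ms <- attr(probes, "streak_range")
  consume <- function(state, x) {
    posterior_transition(agent, posterior_update(agent, state, x))
  }
  emit <- function(state) posterior_summary(agent, state)$prediction
  probe_state_machine(posterior_init(agent), consume, emit, probes, ms)
}

#' @export
streak_probe_curve.heuristic_agent <- function(agent, probes) {
  ms <- attr(probes, "streak_range")
  a <- agent$alpha
  if (agent$rule == "delta" && agent$scope == "unigram") {
    init <- list(p = 0.5)
    consume <- function(s, x) { s$p <- s$p + a * (x - s$p); s }
    emit <- function(s) s$p
  } else if (agent$rule == "delta" && agent$scope == "bigram") {
    init <- list(p00 = 0.5, p11 = 0.5, prev = 0L, fresh = TRUE)
    consume <- function(s, x) {
      if (!s$fresh) {
        if (s$prev == 0L) s$p00 <- s$p00 + a * ((1 - x) - s$p00)
        else s$p11 <- s$p11 + a * (x - s$p11)
      }
      s$fresh <- FALSE; s$prev <- as.integer(x); s
    }
    emit <- function(s) if (s$prev == 1L) s$p11 else 1 - s$p00
  } else if (agent$rule == "leaky" && agent$scope == "unigram") {
    init <- list(n0 = 0, n1 = 0)
    consume <- function(s, x) {
      s$n1 <- a * s$n1 + x; s$n0 <- a * s$n0 + (1 - x); s
    }
    emit <- function(s) (s$n1 + 1) / (s$n1 + s$n0 + 2)
  } else {
    init <- list(n = c(0, 0, 0, 0), prev = 0L, fresh = TRUE)  # n00, n10, n01, n11
    consume <- function(s, x) {
      if (!s$fresh) {
        inc <- c((1 - s$prev) * (1 - x), (1 - s$prev) * x,
                 s$prev * (1 - x), s$prev * x)
        s$n <- a * s$n + inc
      }
      s$fresh <- FALSE; s$prev <- as.integer(x); s
    }
    emit <- function(s) {
      if (s$prev == 1L) (s$n[4L] + 1) / (s$n[4L] + s$n[3L] + 2)
      else 1 - (s$n[1L] + 1) / (s$n[1L] + s$n[2L] + 2)
    }
  }
  probe_state_machine(init, consume, emit, probes, ms)
}

probe_state_machine <- function(init, consume, emit, probes, ms) {
  max_m <- max(ms)
  total <- rep(0, length(ms))
  n_seq <- 0L
  for (cond in probes) {
    q <- cond$query_value
    sv <- cond$streak_value
    for (x in cond$sequences) {
      s <- init
      for (t in seq_along(x)) s <- consume(s, x[t])
      s <- consume(s, q)
      p_before <- emit(s)
      k <- 1L
      for (m in seq_len(max_m)) {
        s <- consume(s, sv)
        while (k <= length(ms) && ms[k] == m) {
          sq <- consume(s, q)
          total[k] <- total[k] + abs(emit(sq) - p_before)
          k <- k + 1L
        }
      }
      n_seq <- n_seq + 1L
    }
  }
  stats::setNames(total / n_seq, ms)
}

#' Higher-level inference test: coupled vs independent training
#'
#' Compares the streak-probe curves of agents trained with coupled change
#' points against agents trained with independent change points. Only an
#' agent that has internalised the coupling should transfer a suspected
#' change in the observed bigram to the unobserved one, producing a larger
#' |p_after - p_before|.
#'
#' @param agents_coupled,agents_independent lists of agents (typically
#'   trained networks) from the two training conditions.
#' @param probes a probe set.
#' @return object of class \code{"streak_transfer"}: per-group curve
#'   matrices (agents x streak lengths), group mean curves, a pooled
#'   one-tailed Welch test (coupled > independent) on per-agent mean
#'   changes, and per-streak-length p-values.
#' @export
streak_transfer_experiment <- function(agents_coupled, agents_independent,
                                       probes) {
  cc <- do.call(rbind, lapply(agents_coupled, streak_probe_curve, probes))
  ci <- do.call(rbind, lapply(agents_independent, streak_probe_curve, probes))
  pooled <- group_statistics(rowMeans(cc), rowMeans(ci),
                             mode = "welch_one_sided")
  per_m <- vapply(seq_len(ncol(cc)), function(j) {
    group_statistics(cc[, j], ci[, j], mode = "welch_one_sided")$p_value
  }, numeric(1))
  structure(list(curves_coupled = cc, curves_independent = ci,
                 mean_coupled = colMeans(cc), mean_independent = colMeans(ci),
                 pooled_test = pooled,
                 p_per_streak = stats::setNames(per_m, colnames(cc))),
            class = "streak_transfer")
}

#' @export
print.streak_transfer <- function(x, ...) {
  cat("<streak transfer> mean |p_after - p_before| (pooled over m):\n")
  cat("  coupled-trained:     ", format(mean(x$mean_coupled), digits = 4), "\n")
  cat("  independent-trained: ", format(mean(x$mean_independent), digits = 4), "\n")
  cat("  one-tailed Welch p = ", format(x$pooled_test$p_value, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Performance versus network size
#'
#' Trains \code{replicates} networks per size on a common dataset and
#' evaluates percent-of-optimal performance on a common test set.
#' Hyperparameters for untabulated sizes come from the nearest tabulated
#' size in log space.
#'
#' @param arch architecture.
#' @param config environment configuration (\code{\link{env_config}}).
#' @param n_grid integer vector of network sizes.
#' @param replicates networks per size.
#' @param n_train_minibatches,minibatch_size training-set size.
#' @param n_test test sequences.
#' @param seed integer seed.
#' @return object of class \code{"complexity_sweep"}: \code{results} data
#'   frame (n_units, replicate, percent) and \code{summary} (per-size mean,
#'   CI half-width, max).
#' @export
complexity_sweep <- function(arch, config, n_grid, replicates = 20L,
                             n_train_minibatches = 400L, minibatch_size = 20L,
                             n_test = 1000L, seed = 1L) {
  train <- generate_dataset(config, n_train_minibatches * minibatch_size,
                            derive_seed(seed, 101L))
  test <- generate_dataset(config, n_test, derive_seed(seed, 102L))
  opt <- optimal_agent(config$structure, config$change_prob)
  L_opt <- agent_log_lik(opt, test)
  L_ch <- chance_log_lik(test)
  rows <- list()
  for (N in n_grid) {
    for (r in seq_len(replicates)) {
      net <- fit_rnn(arch, train, n_units = N,
                     seed = derive_seed(seed, 1000L * N + r),
                     minibatch_size = minibatch_size)
      pct <- percent_optimal(agent_log_lik(net, test), L_opt, L_ch)
      rows[[length(rows) + 1L]] <- data.frame(n_units = N, replicate = r,
                                              percent = pct)
    }
  }
  res <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(res, res$n_units), function(d) {
    n <- nrow(d)
    half <- if (n > 1L) stats::qt(0.975, n - 1L) * stats::sd(d$percent) / sqrt(n)
            else NA_real_
    data.frame(n_units = d$n_units[1L], mean = mean(d$percent), ci = half,
               max = max(d$percent))
  }))
  rownames(summ) <- NULL
  structure(list(results = res, summary = summ, arch = arch,
                 structure = config$structure),
            class = "complexity_sweep")
}

#' @export
print.complexity_sweep <- function(x, ...) {
  cat("<complexity sweep> ", x$arch, " in ", x$structure, "\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Power-law fit of the distance to optimality
#'
#' Fits \eqn{(100 - p) = c (1/N)^a} by least squares on
#' \eqn{(\log N, \log(100 - p))} pairs, where p is the percent-of-optimal
#' performance at network size N.
#'
#' @param n_units network sizes.
#' @param percent percent-of-optimal values, all < 100.
#' @return object of class \code{"power_law_fit"} with \code{coefficient}
#'   (c), \code{exponent} (a) and \code{r_squared} (of the log-log fit, as
#'   a percentage).
#' @export
fit_power_law <- function(n_units, percent) {
  if (any(percent >= 100)) {
    stop("power-law fit requires all percent values below 100")
  }
  fit <- stats::lm(log(100 - percent) ~ log(n_units))
  y <- log(100 - percent)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(coefficient = exp(unname(stats::coef(fit)[1L])),
                 exponent = -unname(stats::coef(fit)[2L]),
                 r_squared = 100 * r2,
                 fit = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("<power law> (100 - p) = c (1/N)^a: c = ",
      format(x$coefficient, digits = 4), ", a = ",
      format(x$exponent, digits = 4), ", R^2 = ",
      format(x$r_squared, digits = 4), "%\n", sep = "")
  invisible(x)
}

#' @rdname fit_power_law
#' @param object a \code{"power_law_fit"}.
#' @param n_units sizes at which to predict performance.
#' @param ... unused.
#' @export
predict.power_law_fit <- function(object, n_units, ...) {
  100 - object$coefficient * n_units^(-object$exponent)
}

#' Group comparison statistics
#'
#' The statistical tests used throughout the analyses: Welch's two
#' independent samples t-test (two-sided or one-sided testing
#' \code{mean(a) > mean(b)}), the paired one-sided t-test on \code{a - b},
#' and the interaction F-test of a 2 x 2 factorial design.
#'
#' @param a,b numeric samples. For \code{mode = "interaction_f"}, each is a
#'   list of two numeric vectors: \code{a} holds the two cells at the first
#'   level of factor one, \code{b} at the second level; the list position
#'   is the level of factor two.
#' @param mode test to run.
#' @return list with \code{statistic}, \code{df}, \code{p_value}, and
#'   \code{degenerate} flag (paired test with zero-variance differences).
#' @export
group_statistics <- function(a, b,
                             mode = c("welch_two_sided", "welch_one_sided",
                                      "paired_one_sided", "interaction_f")) {
  mode <- match.arg(mode)
  if (mode == "interaction_f") {
    stopifnot(is.list(a), is.list(b), length(a) == 2L, length(b) == 2L)
    if (any(lengths(c(a, b)) < 2L)) stop("each cell needs n >= 2")
    y <- c(a[[1L]], a[[2L]], b[[1L]], b[[2L]])
    f1 <- factor(rep(c("a", "a", "b", "b"), times = lengths(c(a, b))))
    f2 <- factor(rep(c("1", "2", "1", "2"), times = lengths(c(a, b))))
    an <- stats::anova(stats::lm(y ~ f1 * f2))
    return(list(statistic = an["f1:f2", "F value"],
                df = c(an["f1:f2", "Df"], an["Residuals", "Df"]),
                p_value = an["f1:f2", "Pr(>F)"], degenerate = FALSE))
  }
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  if (mode == "paired_one_sided") {
    stopifnot(length(a) == length(b))
    d <- a - b
    if (stats::sd(d) <= 1e-12 * (abs(mean(d)) + 1)) {
      warning("zero-variance differences: degenerate paired test")
      return(list(statistic = if (mean(d) > 0) Inf else -Inf,
                  df = length(d) - 1L,
                  p_value = if (mean(d) > 0) 0 else 1, degenerate = TRUE))
    }
    tt <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE,
                        alternative = if (mode == "welch_one_sided")
                          "greater" else "two.sided")
  }
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, degenerate = FALSE)
}
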