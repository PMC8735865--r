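#' Exact Bayesian observer on a discretised probability grid
#'
#' Constructs the ideal observer for one of the three volatile environments.
#' Inference inverts the generative process with a hidden-Markov forward
#' filter: the latent probability interval \[0,1\] is discretised into
#' \code{n_bins} equal-width bins (represented by their centres), the
#' change-point hazard acts as the transition kernel (mass is mixed with the
#' uniform distribution with probability \code{change_prob}; jointly over
#' both bigram probabilities when change points are coupled, independently
#' otherwise), and each observation multiplies in its Bernoulli likelihood.
#' The emitted prediction is the mean of the predictive posterior over the
#' next step's relevant latent probability.
#'
#' @param structure environment structure being inverted (may differ from
#'   the structure that generated a sequence, for cross-environment tests).
#' @param change_prob assumed per-step change probability.
#' @param n_bins number of grid bins per latent dimension (default 20).
#' @return object of class \code{"optimal_agent"}.
#' @export
optimal_agent <- function(structure = c("unigram", "bigram_independent",
                                        "bigram_coupled"),
                          change_prob = 1 / 75, n_bins = 20L) {
  structure <- match.arg(structure)
  stopifnot(change_prob >= 0, change_prob <= 1, n_bins >= 2L)
  n_bins <- as.integer(n_bins)
  structure(list(structure = structure, change_prob = change_prob,
                 n_bins = n_bins,
                 bin_values = (seq_len(n_bins) - 0.5) / n_bins),
            class = "optimal_agent")
}

#' @export
print.optimal_agent <- function(x, ...) {
  cat("<optimal agent> ", x$structure, ", pc = ",
      format(x$change_prob, digits = 6), ", ", x$n_bins,
      " bins per latent\n", sep = "")
  invisible(x)
}

#' Posterior-state operations of the forward filter
#'
#' Low-level building blocks of the filter, exposed for verification. A
#' posterior state is a list with \code{mass} (vector of length
#' \code{n_bins} for the unigram observer, or an \code{n_bins x n_bins}
#' matrix over (p(0|0), p(1|1)) for the bigram observers) and
#' \code{prev_obs}, the last observation consumed (0 before any).
#'
#' \code{posterior_init} returns the uniform prior; \code{posterior_transition}
#' applies the change-point hazard; \code{posterior_update} multiplies in the
#' Bernoulli likelihood of \code{obs} given \code{prev_obs} and renormalises;
#' \code{posterior_summary} returns the prediction (expected probability that
#' the next observation is 1) and, per latent marginal, the posterior mean,
#' standard deviation and log precision \eqn{\psi = -\log SD}.
#'
#' @param agent an \code{\link{optimal_agent}}.
#' @param state a posterior state.
#' @param obs binary observation.
#' @name posterior_ops
NULL

#' @rdname posterior_ops
#' @export
posterior_init <- function(agent) {
  n <- agent$n_bins
  mass <- if (agent$structure == "unigram") rep(1 / n, n)
          else matrix(1 / n^2, n, n)
  list(mass = mass, prev_obs = 0L)
}

#' @rdname posterior_ops
#' @export
posterior_transition <- function(agent, state) {
  pc <- agent$change_prob
  n <- agent$n_bins
  m <- state$mass
  if (agent$structure == "unigram") {
    state$mass <- (1 - pc) * m + pc / n
  } else if (agent$structure == "bigram_independent") {
    # kernel factorises over the two latent dimensions
    a <- (1 - pc) * m + (pc / n) * matrix(colSums(m), n, n, byrow = TRUE)
    state$mass <- (1 - pc) * a + (pc / n) * matrix(rowSums(a), n, n)
  } else {
    state$mass <- (1 - pc) * m + pc / n^2
  }
  state
}

#' @rdname posterior_ops
#' @export
posterior_update <- function(agent, state, obs) {
  v <- agent$bin_values
  n <- agent$n_bins
  obs <- as.integer(obs)
  if (agent$structure == "unigram") {
    lik <- if (obs == 1L) v else 1 - v
    m <- state$mass * lik
  } else if (state$prev_obs == 1L) {
    lik <- if (obs == 1L) v else 1 - v       # acts on the p(1|1) dimension
    m <- state$mass * matrix(lik, n, n, byrow = TRUE)
  } else {
    lik <- if (obs == 0L) v else 1 - v       # acts on the p(0|0) dimension
    m <- state$mass * lik
  }
  tot <- sum(m)
  if (tot <= 0) stop("posterior mass underflow in bayes update")
  state$mass <- m / tot
  state$prev_obs <- obs
  state
}

#' @rdname posterior_ops
#' @export
posterior_summary <- function(agent, state) {
  v <- agent$bin_values
  if (agent$structure == "unigram") {
    marg <- matrix(state$mass, ncol = 1L)
  } else {
    marg <- cbind(rowSums(state$mass), colSums(state$mass))
  }
  mean_ <- colSums(marg * v)
  sd_ <- sqrt(pmax(colSums(marg * v^2) - mean_^2, 0))
  if (any(sd_ <= 0)) stop("degenerate posterior: zero standard deviation")
  pred <- if (agent$structure == "unigram") mean_[1L]
          else if (state$prev_obs == 1L) mean_[2L] else 1 - mean_[1L]
  list(prediction = pred, mean = mean_, sd = sd_, psi = -log(sd_))
}

#' Run the ideal observer on a sequence
#'
#' Filters the observations and returns the full posterior trace. The
#' predictions vector has length T+1 with \code{predictions[k]} the
#' probability assigned to the k-th observation being 1 given the first
#' k-1 observations; the first entry (uniform prior, no data) is 0.5 and
#' the last entry is the prediction emitted after the final observation.
#' The per-latent posterior mean, SD and log precision \eqn{\psi} are
#' aligned the same way (row k conditions on the first k-1 observations,
#' for the predictive posterior over the latent at step k).
#'
#' @param object an \code{\link{optimal_agent}}.
#' @param sequence a \code{"seqvol_seq"} object or a binary integer vector.
#' @param ... unused.
#' @return object of class \code{"posterior_trace"}: list with
#'   \code{predictions} (length T+1), matrices \code{post_mean},
#'   \code{post_sd}, \code{psi} ((T+1) x latents) and scalar
#'   \code{log_lik}, the sequence log likelihood (natural log, one term per
#'   observation from the second onwards, matching the self-supervised
#'   prediction score).
#' @export
predict.optimal_agent <- function(object, sequence, ...) {
  x <- observation_vector(sequence)
  T_ <- length(x)
  nl <- n_latents(object$structure)
  predictions <- numeric(T_ + 1L)
  post_mean <- matrix(NA_real_, T_ + 1L, nl)
  post_sd <- matrix(NA_real_, T_ + 1L, nl)
  state <- posterior_init(object)
  for (k in seq_len(T_ + 1L)) {
    s <- posterior_summary(object, state)
    predictions[k] <- s$prediction
    post_mean[k, ] <- s$mean
    post_sd[k, ] <- s$sd
    if (k <= T_) {
      state <- posterior_update(object, state, x[k])
      state <- posterior_transition(object, state)
    }
  }
  ln <- latent_names(if (object$structure == "unigram") "unigram"
                     else "bigram_independent")
  colnames(post_mean) <- ln
  colnames(post_sd) <- ln
  structure(list(predictions = predictions,
                 post_mean = post_mean,
                 post_sd = post_sd,
                 psi = -log(post_sd),
                 log_lik = sequence_log_lik(predictions, x),
                 structure = object$structure),
            class = c("posterior_trace", "agent_trace"))
}

observation_vector <- function(sequence) {
  x <- if (inherits(sequence, "seqvol_seq")) sequence$x else sequence
  x <- as.integer(x)
  if (length(x) < 1L || any(is.na(x)) || any(x != 0L & x != 1L)) {
    stop("observations must be a non-empty binary (0/1) vector")
  }
  x
}

# Log likelihood of a prediction trace (length T+1 convention): the k-th
# observation is scored by the prediction made from the first k-1
# observations, for k = 2..T. The first observation is predicted only by
# the data-free prior, identical across agents up to their prior output, and
# is excluded so that chance level is exactly -(T-1) log 2.
sequence_log_lik <- function(predictions, x) {
  T_ <- length(x)
  k <- 2:T_
  sum(log(ifelse(x[k] == 1L, predictions[k], 1 - predictions[k])))
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat("<posterior trace> ", x$structure, ", T = ",
      length(x$predictions) - 1L, ", log lik = ",
      format(x$log_lik, digits = 6), "\n", sep = "")
  invisible(x)
}
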