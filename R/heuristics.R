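#' Heuristic prediction agents
#'
#' The four heuristic solutions form a 2 x 2 family: the estimated variables
#' are either a single base rate (\code{scope = "unigram"}) or the two
#' transition probabilities p(0|0) and p(1|1) (\code{scope = "bigram"}), and
#' the update rule is either the Rescorla-Wagner \code{"delta"} rule
#' (estimate moves a fixed fraction \code{alpha} towards each prediction
#' error) or the \code{"leaky"} rule (exponentially discounted event counts
#' with decay \code{alpha}, estimate = Laplace-smoothed ratio
#' (n1+1)/(n1+n0+2), i.e. the mean of an approximate Beta posterior).
#' Estimates start at 0.5 (delta) or zero counts (leaky); bigram agents
#' update only the estimate whose context (previous observation) occurred,
#' and predict p(1|1) after a 1 and 1-p(0|0) after a 0 (the observation
#' before the sequence is taken to be 0).
#'
#' @param rule \code{"delta"} or \code{"leaky"}.
#' @param scope \code{"unigram"} or \code{"bigram"}.
#' @param alpha the single free parameter: learning rate in (0,1) for the
#'   delta rule, count decay in (0,1] for the leaky rule.
#' @return object of class \code{"heuristic_agent"}.
#' @export
heuristic_agent <- function(rule = c("delta", "leaky"),
                            scope = c("unigram", "bigram"), alpha) {
  rule <- match.arg(rule)
  scope <- match.arg(scope)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha)) {
    stop("`alpha` must be a single number")
  }
  if (rule == "delta" && (alpha <= 0 || alpha >= 1)) {
    stop("delta-rule alpha must lie in (0, 1)")
  }
  if (rule == "leaky" && (alpha <= 0 || alpha > 1)) {
    stop("leaky-rule alpha must lie in (0, 1]")
  }
  structure(list(rule = rule, scope = scope, alpha = alpha),
            class = "heuristic_agent")
}

#' @export
print.heuristic_agent <- function(x, ...) {
  cat("<heuristic agent> ", x$rule, " / ", x$scope, ", alpha = ",
      format(x$alpha, digits = 6), "\n", sep = "")
  if (!is.null(x$fit)) {
    cat("  fitted by SGD: ", length(x$fit$loss), " minibatches, final loss ",
        format(x$fit$loss[length(x$fit$loss)], digits = 6), "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.heuristic_agent <- function(object, ...) c(alpha = object$alpha)

# Forward pass of a heuristic on one sequence; optionally carries the
# derivative of every prediction with respect to alpha (forward-mode),
# which backs the SGD fit (equivalent to backpropagation through the
# recursion, the recursion being linear in its state).
heuristic_forward <- function(rule, scope, alpha, x, grad = FALSE) {
  T_ <- length(x)
  pred <- numeric(T_ + 1L)
  dpred <- numeric(T_ + 1L)
  a <- alpha
  if (rule == "delta" && scope == "unigram") {
    p <- 0.5; dp <- 0
    pred[1L] <- p
    for (k in seq_len(T_)) {
      err <- x[k] - p
      dp <- dp * (1 - a) + err
      p <- p + a * err
      pred[k + 1L] <- p; dpred[k + 1L] <- dp
    }
  } else if (rule == "delta" && scope == "bigram") {
    # estimates update on observed transitions (x_t, x_{t+1}) only: the
    # first observation has no real predecessor and updates nothing
    p00 <- 0.5; p11 <- 0.5; d00 <- 0; d11 <- 0
    prev <- 0L
    pred[1L] <- 1 - p00
    for (k in seq_len(T_)) {
      if (k > 1L) {
        if (prev == 0L) {
          err <- (1 - x[k]) - p00
          d00 <- d00 * (1 - a) + err
          p00 <- p00 + a * err
        } else {
          err <- x[k] - p11
          d11 <- d11 * (1 - a) + err
          p11 <- p11 + a * err
        }
      }
      prev <- x[k]
      if (prev == 1L) { pred[k + 1L] <- p11; dpred[k + 1L] <- d11 }
      else { pred[k + 1L] <- 1 - p00; dpred[k + 1L] <- -d00 }
    }
  } else if (rule == "leaky" && scope == "unigram") {
    n0 <- 0; n1 <- 0; dn0 <- 0; dn1 <- 0
    pred[1L] <- 0.5
    for (k in seq_len(T_)) {
      dn1 <- n1 + a * dn1; dn0 <- n0 + a * dn0
      n1 <- a * n1 + x[k]; n0 <- a * n0 + (1 - x[k])
      den <- n1 + n0 + 2
      pred[k + 1L] <- (n1 + 1) / den
      dpred[k + 1L] <- (dn1 * den - (n1 + 1) * (dn1 + dn0)) / den^2
    }
  } else {
    n <- c(n00 = 0, n10 = 0, n01 = 0, n11 = 0)
    dn <- c(0, 0, 0, 0)
    prev <- 0L
    pred[1L] <- 0.5
    for (k in seq_len(T_)) {
      if (k > 1L) {  # counts track observed transitions only
        inc <- c((1 - prev) * (1 - x[k]), (1 - prev) * x[k],
                 prev * (1 - x[k]), prev * x[k])
        dn <- n + a * dn
        n <- a * n + inc
      }
      prev <- x[k]
      if (prev == 1L) {
        den <- n[4L] + n[3L] + 2
        pred[k + 1L] <- (n[4L] + 1) / den
        dpred[k + 1L] <- (dn[4L] * den - (n[4L] + 1) * (dn[4L] + dn[3L])) / den^2
      } else {
        den <- n[1L] + n[2L] + 2
        pred[k + 1L] <- 1 - (n[1L] + 1) / den
        dpred[k + 1L] <- -(dn[1L] * den - (n[1L] + 1) * (dn[1L] + dn[2L])) / den^2
      }
    }
  }
  if (grad) list(predictions = pred, dpredictions = dpred)
  else list(predictions = pred)
}

#' Run a heuristic agent on a sequence
#'
#' @param object a \code{\link{heuristic_agent}}.
#' @param sequence a \code{"seqvol_seq"} or binary vector.
#' @param ... unused.
#' @return object of class \code{"agent_trace"}: \code{predictions} of
#'   length T+1 (first entry is the pre-observation prediction 0.5) and
#'   \code{log_lik}.
#' @export
predict.heuristic_agent <- function(object, sequence, ...) {
  x <- observation_vector(sequence)
  fw <- heuristic_forward(object$rule, object$scope, object$alpha, x)
  structure(list(predictions = fw$predictions,
                 log_lik = sequence_log_lik(fw$predictions, x),
                 agent = paste(object$rule, object$scope, sep = "_")),
            class = "agent_trace")
}

#' @export
print.agent_trace <- function(x, ...) {
  cat("<agent trace> ", if (!is.null(x$agent)) x$agent else "", ", T = ",
      length(x$predictions) - 1L, ", log lik = ",
      format(x$log_lik, digits = 6), "\n", sep = "")
  invisible(x)
}

# Mean cross-entropy loss and its alpha-gradient on a set of sequences
# (mean over scored time steps within a sequence, mean over sequences).
heuristic_loss_grad <- function(rule, scope, alpha, xs) {
  loss <- 0; grad <- 0
  for (x in xs) {
    fw <- heuristic_forward(rule, scope, alpha, x, grad = TRUE)
    T_ <- length(x)
    k <- 2:T_
    p <- fw$predictions[k]
    dp <- fw$dpredictions[k]
    obs1 <- x[k] == 1L
    lik <- ifelse(obs1, p, 1 - p)
    loss <- loss - mean(log(lik))
    grad <- grad - mean(ifelse(obs1, dp / p, -dp / (1 - p)))
  }
  list(loss = loss / length(xs), grad = grad / length(xs))
}

#' Fit a heuristic agent's free parameter by stochastic gradient descent
#'
#' Initialises \code{alpha} from a value r drawn log-uniformly on
#' \[10^-2.5, 10^-0.5\] (alpha = r for the delta rule, exp(-r) for the
#' leaky rule) and performs one pass of minibatch SGD on the prediction
#' cross-entropy, with gradients propagated through the heuristic recursion.
#' After each step alpha is projected back into its valid range.
#'
#' @inheritParams heuristic_agent
#' @param sequences training sequences (list of \code{"seqvol_seq"} or
#'   binary vectors).
#' @param learning_rate SGD step size (default 3e-3, the value selected for
#'   all heuristic types).
#' @param minibatch_size sequences per gradient step (default 20).
#' @param seed integer seed (controls initialisation and data order).
#' @return a fitted \code{"heuristic_agent"} with a \code{fit} field
#'   (initial alpha, alpha path, minibatch loss path).
#' @export
fit_heuristic <- function(rule = c("delta", "leaky"),
                          scope = c("unigram", "bigram"),
                          sequences, learning_rate = 3e-3,
                          minibatch_size = 20L, seed = 1L) {
  rule <- match.arg(rule)
  scope <- match.arg(scope)
  if (length(sequences) == 0L) stop("empty training dataset")
  xs <- lapply(sequences, observation_vector)
  lo <- 1e-4
  hi <- if (rule == "delta") 1 - 1e-4 else 1
  with_seed(derive_seed(seed, 1L), {
    r <- 10^stats::runif(1L, -2.5, -0.5)
    alpha <- if (rule == "delta") r else exp(-r)
    xs <- xs[sample.int(length(xs))]
    starts <- seq(1L, length(xs), by = minibatch_size)
    losses <- numeric(length(starts))
    path <- numeric(length(starts))
    for (b in seq_along(starts)) {
      idx <- starts[b]:min(starts[b] + minibatch_size - 1L, length(xs))
      lg <- heuristic_loss_grad(rule, scope, alpha, xs[idx])
      alpha <- min(max(alpha - learning_rate * lg$grad, lo), hi)
      losses[b] <- lg$loss
      path[b] <- alpha
    }
    agent <- heuristic_agent(rule, scope, alpha)
    agent$fit <- list(alpha_init = if (rule == "delta") r else exp(-r),
                      alpha_path = path, loss = losses,
                      learning_rate = learning_rate, seed = seed)
    agent
  })
}
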