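#' Optimised training and initialisation hyperparameters
#'
#' Returns the packaged hyperparameter record for a given environment,
#' architecture and network size: the initial Adam step size \code{eta0},
#' the input-weight initialisation SD \code{sigma0_x}, the recurrent-weight
#' initialisation SD \code{sigma0_h}, and the diagonal recurrent-weight
#' initialisation mean \code{mu0_h_ii} (nonzero only for some networks
#' without lateral connections, where it counters vanishing gradients).
#' If no record exists for the requested size and \code{fallback} is TRUE,
#' the record for the nearest tabulated size in logarithmic space is used.
#'
#' @param environment \code{"unigram"} or \code{"bigram"} (the coupled and
#'   independent bigram variants share hyperparameters); full structure
#'   names are accepted and mapped.
#' @param arch one of \code{"gated"}, \code{"no_gating"},
#'   \code{"no_lateral"}, \code{"frozen_recurrence"}.
#' @param n_units requested number of recurrent units.
#' @param fallback allow the nearest-size fallback.
#' @return one-row data frame with class \code{"hyperparameter_record"}.
#' @export
load_hyperparameters <- function(environment, arch, n_units = 11L,
                                 fallback = TRUE) {
  environment <- hp_environment(environment)
  arch <- match.arg(arch, c("gated", "no_gating", "no_lateral",
                            "frozen_recurrence"))
  tab <- hyperparameter_table()
  rows <- tab[tab$environment == environment & tab$arch == arch, ]
  if (nrow(rows) == 0L) stop("no hyperparameter rows for this combination")
  hit <- rows[rows$n_units == n_units, ]
  if (nrow(hit) == 0L) {
    if (!fallback) {
      stop("no hyperparameter row for N = ", n_units,
           " and nearest-size fallback is disabled")
    }
    hit <- rows[which.min(abs(log(rows$n_units) - log(n_units))), ]
  }
  hit <- hit[1L, , drop = FALSE]
  rownames(hit) <- NULL
  class(hit) <- c("hyperparameter_record", "data.frame")
  hit
}

hp_environment <- function(environment) {
  switch(environment,
         unigram = "unigram",
         bigram = "bigram",
         bigram_independent = "bigram",
         bigram_coupled = "bigram",
         stop("unknown environment: ", environment))
}

hyperparameter_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "hyperparameters.csv",
                          package = "seqvol", mustWork = TRUE)
      cache <<- utils::read.csv(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

#' Initialise a recurrent network
#'
#' Creates an untrained network of one of the four architectures. Biases
#' are drawn uniformly on \[-1/N, 1/N\]; output weights from a normal with
#' SD 1/N; input weights from a normal with SD \code{sigma0_x}; recurrent
#' weights from a normal with SD \code{sigma0_h}, off-diagonal mean 0 and
#' diagonal mean \code{mu0_h_ii}. Networks without lateral connections have
#' their off-diagonal recurrent weights fixed at exactly 0; networks
#' without gating carry no reset/update-gate parameters.
#'
#' @inheritParams load_hyperparameters
#' @param hp a hyperparameter record (default: looked up from the packaged
#'   table).
#' @param seed integer seed for the parameter draw.
#' @return object of class \code{"rnn_agent"} (untrained).
#' @export
init_rnn <- function(arch = c("gated", "no_gating", "no_lateral",
                              "frozen_recurrence"),
                     environment, n_units = 11L, hp = NULL, seed = 1L) {
  arch <- match.arg(arch)
  n_units <- as.integer(n_units)
  if (is.null(hp)) hp <- load_hyperparameters(environment, arch, n_units)
  N <- n_units
  params <- with_seed(derive_seed(seed, 1L), {
    ub <- function() stats::runif(N, -1 / N, 1 / N)
    wx <- function() stats::rnorm(N, 0, hp$sigma0_x)
    wh <- function() {
      W <- matrix(stats::rnorm(N * N, 0, hp$sigma0_h), N, N)
      diag(W) <- stats::rnorm(N, hp$mu0_h_ii, hp$sigma0_h)
      if (arch == "no_lateral") W[row(W) != col(W)] <- 0
      W
    }
    p <- list(arch = arch, n_units = N)
    if (arch != "no_gating") {
      p$Wxr <- wx(); p$bxr <- ub(); p$Whr <- wh(); p$bhr <- ub()
      p$Wxz <- wx(); p$bxz <- ub(); p$Whz <- wh(); p$bhz <- ub()
    }
    p$Wxh <- wx(); p$bxh <- ub(); p$Whh <- wh(); p$bhh <- ub()
    p$whp <- stats::rnorm(N, 0, 1 / N)
    p$bhp <- stats::runif(1, -1 / N, 1 / N)
    p
  })
  structure(list(arch = arch, n_units = N,
                 environment = hp_environment(environment),
                 hp = hp, seed = as.integer(seed),
                 params = params, init_params = params,
                 trained = FALSE, loss = numeric(0)),
            class = "rnn_agent")
}

#' Train a recurrent network by backpropagation through time
#'
#' Initialises a network (see \code{\link{init_rnn}}) and makes a single
#' pass over the training sequences with minibatch Adam (moment decays 0.9
#' and 0.999, epsilon 1e-8, initial step size \code{eta0} from the
#' hyperparameter record). The objective is the self-supervised prediction
#' cross-entropy: the output emitted after each observation is scored
#' against the next observation (the final output of a sequence has no
#' target and is excluded), averaged over time steps and sequences in the
#' minibatch. Gradients flow through the full sequence. For
#' \code{"frozen_recurrence"} only the output weights and bias are updated;
#' for \code{"no_lateral"} off-diagonal recurrent weights stay at zero.
#' Sequence order is shuffled deterministically from \code{seed}.
#'
#' @inheritParams init_rnn
#' @param sequences training sequences (list of \code{"seqvol_seq"} or
#'   binary vectors; all the same length).
#' @param minibatch_size sequences per gradient update (default 20).
#' @param environment hyperparameter environment; inferred from the first
#'   sequence's structure when omitted.
#' @return a trained \code{"rnn_agent"} with the per-minibatch training
#'   loss in \code{$loss} and the initial parameters in
#'   \code{$init_params}.
#' @export
fit_rnn <- function(arch = c("gated", "no_gating", "no_lateral",
                             "frozen_recurrence"),
                    sequences, n_units = 11L, hp = NULL, seed = 1L,
                    minibatch_size = 20L, environment = NULL) {
  arch <- match.arg(arch)
  if (is.null(environment)) {
    if (!inherits(sequences[[1L]], "seqvol_seq")) {
      stop("`environment` must be given when sequences are raw vectors")
    }
    environment <- sequences[[1L]]$structure
  }
  net <- init_rnn(arch, environment, n_units, hp, seed)
  xs <- lapply(sequences, observation_vector)
  T_ <- length(xs[[1L]])
  if (any(vapply(xs, length, integer(1)) != T_)) {
    stop("all training sequences must have equal length")
  }
  ord <- with_seed(derive_seed(seed, 2L), sample.int(length(xs)))
  X <- do.call(rbind, xs[ord])
  storage.mode(X) <- "integer"
  res <- cpp_train(net$params, X, as.integer(minibatch_size),
                   net$hp$eta0, 0.9, 0.999, 1e-8,
                   train_recurrent = arch != "frozen_recurrence",
                   lateral = arch != "no_lateral")
  net$params <- res$params
  net$loss <- as.numeric(res$loss)
  net$trained <- TRUE
  net
}

#' Run a network on a sequence
#'
#' @param object an \code{"rnn_agent"}.
#' @param sequence a \code{"seqvol_seq"} or binary vector.
#' @param ... unused.
#' @return object of class \code{"agent_trace"}: \code{predictions} of
#'   length T+1 (entry k is the output after the first k-1 observations;
#'   the first entry is the data-free output from the zero hidden state),
#'   \code{hidden} (T x N matrix of recurrent activations, row t after
#'   consuming observation t) and \code{log_lik}.
#' @export
predict.rnn_agent <- function(object, sequence, ...) {
  x <- observation_vector(sequence)
  fw <- cpp_forward(object$params, x)
  structure(list(predictions = as.numeric(fw$predictions),
                 hidden = fw$hidden,
                 log_lik = sequence_log_lik(as.numeric(fw$predictions), x),
                 agent = object$arch),
            class = "agent_trace")
}

#' Single-step network dynamics
#'
#' Pure-R implementation of one update of the recurrent state (used by the
#' perturbation experiment, where a modified hidden state must be advanced
#' by hand) and of the output unit. \code{network_step} consumes one
#' observation from state \code{h}; \code{network_output} maps a state to
#' the prediction through the logistic output unit.
#'
#' @param net an \code{"rnn_agent"} (or its parameter list).
#' @param h numeric state vector of length N.
#' @param x binary observation.
#' @return \code{network_step}: the new state; \code{network_output}: the
#'   prediction in (0,1).
#' @export
network_step <- function(net, h, x) {
  p <- net_params(net)
  if (length(h) != p$n_units) stop("state dimension does not match n_units")
  drive <- function(W) as.numeric(W %*% h)
  if (p$arch == "no_gating") {
    tanh(p$Wxh * x + p$bxh + drive(p$Whh) + p$bhh)
  } else {
    r <- stats::plogis(p$Wxr * x + p$bxr + drive(p$Whr) + p$bhr)
    z <- stats::plogis(p$Wxz * x + p$bxz + drive(p$Whz) + p$bhz)
    cand <- tanh(p$Wxh * x + p$bxh + r * drive(p$Whh) + p$bhh)
    z * h + (1 - z) * cand
  }
}

#' @rdname network_step
#' @export
network_output <- function(net, h) {
  p <- net_params(net)
  stats::plogis(sum(p$whp * h) + p$bhp)
}

net_params <- function(net) {
  if (inherits(net, "rnn_agent")) net$params
  else if (is.list(net) && !is.null(net$arch)) net
  else stop("expected an rnn_agent or a parameter list")
}

#' @export
print.rnn_agent <- function(x, ...) {
  cat("<recurrent network> ", x$arch, ", N = ", x$n_units, ", ",
      x$environment, " hyperparameters",
      if (x$trained) ", trained" else ", untrained", "\n", sep = "")
  if (x$trained) {
    cat("  ", length(x$loss), " minibatches, final training loss ",
        format(x$loss[length(x$loss)], digits = 6), "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.rnn_agent <- function(object, ...) {
  object$params[setdiff(names(object$params), c("arch", "n_units"))]
}

#' @export
summary.rnn_agent <- function(object, ...) {
  n_par <- sum(vapply(coef(object), length, integer(1)))
  cat("Recurrent network (", object$arch, "), ", object$n_units,
      " units, ", n_par, " parameters\n", sep = "")
  cat("Hyperparameters: eta0 = ", object$hp$eta0, ", sigma0_x = ",
      object$hp$sigma0_x, ", sigma0_h = ", object$hp$sigma0_h,
      ", mu0_h_ii = ", object$hp$mu0_h_ii, "\n", sep = "")
  if (object$trained) {
    cat("Trained on ", length(object$loss), " minibatches; final loss ",
        format(object$loss[length(object$loss)], digits = 6),
        " (chance ", format(log(2), digits = 6), ")\n", sep = "")
  } else cat("Untrained\n")
  invisible(object)
}
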