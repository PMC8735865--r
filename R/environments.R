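#' Environment configuration
#'
#' Defines one of the three generative processes for binary sequences with
#' latent probabilities that are resampled at hidden change points:
#' \describe{
#'   \item{unigram}{one latent base rate \eqn{p(1)}; at each step the
#'     observation is Bernoulli with that rate.}
#'   \item{bigram_independent}{two latent transition (bigram) probabilities
#'     \eqn{p(0|0)} and \eqn{p(1|1)}, each resampled independently.}
#'   \item{bigram_coupled}{same two bigram probabilities but their change
#'     points always occur simultaneously.}
#' }
#' At every time step after the first, each latent probability is redrawn
#' uniformly on \[0,1\] with probability \code{change_prob}, otherwise it is
#' carried over. Defaults follow the study conditions: sequences of
#' \code{length} 380 observations with change probability 1/75.
#'
#' @param structure one of \code{"unigram"}, \code{"bigram_independent"},
#'   \code{"bigram_coupled"}.
#' @param change_prob per-step probability of a change point, in \[0,1\].
#' @param length number of observations per sequence (>= 1).
#' @return an object of class \code{"seqvol_env"}.
#' @export
env_config <- function(structure = c("unigram", "bigram_independent",
                                     "bigram_coupled"),
                       change_prob = 1 / 75, length = 380L) {
  structure <- match.arg(structure)
  if (!is.numeric(change_prob) || length(change_prob) != 1L ||
      is.na(change_prob) || change_prob < 0 || change_prob > 1) {
    stop("`change_prob` must be a single probability in [0, 1]")
  }
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("`length` must be >= 1")
  structure(list(structure = structure,
                 change_prob = change_prob,
                 length = length),
            class = "seqvol_env")
}

#' @export
print.seqvol_env <- function(x, ...) {
  cat("<seqvol environment>\n")
  cat("  structure:   ", x$structure, "\n", sep = "")
  cat("  change prob: ", format(x$change_prob, digits = 6), "\n", sep = "")
  cat("  length (T):  ", x$length, "\n", sep = "")
  invisible(x)
}

n_latents <- function(structure) if (structure == "unigram") 1L else 2L

latent_names <- function(structure) {
  if (structure == "unigram") "p1" else c("p0given0", "p1given1")
}

# Deterministic per-sequence seed derived from (seed, index) so datasets are
# reproducible regardless of generation order. MINSTD-style mixing; all
# intermediate products stay below 2^53 and results below 2^31.
derive_seed <- function(seed, index) {
  m <- 2147483647
  s <- abs(as.numeric(seed)) %% m
  s <- (s * 48271 + 1) %% m
  s <- (s + as.numeric(index)) %% m
  s <- (s * 48271 + 1) %% m
  as.integer(max(1, s))
}

# Evaluate expr under a local RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Piecewise-constant latent trajectory: values redrawn where flags are TRUE
# (the first step always holds the initial draw).
latents_from_flags <- function(flags) {
  T_ <- length(flags)
  draw_at <- flags
  draw_at[1L] <- TRUE
  vals <- stats::runif(sum(draw_at))
  vals[cumsum(draw_at)]
}

sample_observations <- function(structure, latents) {
  T_ <- nrow(latents)
  u <- stats::runif(T_)
  x <- integer(T_)
  if (structure == "unigram") {
    x <- as.integer(u < latents[, 1L])
  } else {
    prev <- 0L  # at t = 0 the previous observation is taken to be 0
    for (t in seq_len(T_)) {
      p1 <- if (prev == 1L) latents[t, 2L] else 1 - latents[t, 1L]
      x[t] <- as.integer(u[t] < p1)
      prev <- x[t]
    }
  }
  x
}

make_sequence <- function(config, x, latents, flags) {
  colnames(latents) <- latent_names(config$structure)
  colnames(flags) <- latent_names(config$structure)
  structure(list(x = x, latents = latents, change_flags = flags,
                 structure = config$structure,
                 change_prob = config$change_prob),
            class = "seqvol_seq")
}

#' Generate one sequence from an environment
#'
#' Draws the latent probability trajectories (initial values uniform on
#' \[0,1\], redrawn at change points occurring with the configured
#' probability at every step after the first) and then samples the binary
#' observations. For bigram structures the Bernoulli parameter at step t is
#' \eqn{p(1|1)_t} when the previous observation was 1 and
#' \eqn{1 - p(0|0)_t} otherwise; the observation preceding the sequence is
#' taken to be 0.
#'
#' @param config a \code{\link{env_config}} object.
#' @param seed integer seed for this sequence (the caller's RNG state is
#'   left untouched).
#' @return an object of class \code{"seqvol_seq"}: list with integer vector
#'   \code{x} (observations, length T), matrix \code{latents} (T x number of
#'   latent probabilities) and logical matrix \code{change_flags} marking
#'   redraw events (never at the first step).
#' @export
generate_sequence <- function(config, seed) {
  stopifnot(inherits(config, "seqvol_env"))
  T_ <- config$length
  pc <- config$change_prob
  with_seed(seed, {
    if (config$structure == "unigram") {
      flags <- c(FALSE, stats::runif(T_ - 1L) < pc)
      lat <- matrix(latents_from_flags(flags), ncol = 1L)
      fl <- matrix(flags, ncol = 1L)
    } else if (config$structure == "bigram_independent") {
      f1 <- c(FALSE, stats::runif(T_ - 1L) < pc)
      f2 <- c(FALSE, stats::runif(T_ - 1L) < pc)
      lat <- cbind(latents_from_flags(f1), latents_from_flags(f2))
      fl <- cbind(f1, f2)
    } else {
      f <- c(FALSE, stats::runif(T_ - 1L) < pc)
      lat <- cbind(latents_from_flags(f), latents_from_flags(f))
      fl <- cbind(f, f)
    }
    x <- sample_observations(config$structure, lat)
    make_sequence(config, x, lat, fl)
  })
}

#' Generate a dataset of sequences
#'
#' Each sequence uses an RNG stream derived from \code{(seed, index)}, so a
#' dataset is reproducible independently of generation order.
#'
#' @inheritParams generate_sequence
#' @param n number of sequences.
#' @return list of \code{"seqvol_seq"} objects.
#' @export
generate_dataset <- function(config, n, seed) {
  lapply(seq_len(n), function(i) generate_sequence(config, derive_seed(seed, i)))
}

#' @rdname generate_dataset
#' @param object a \code{"seqvol_env"} configuration.
#' @param nsim number of sequences to simulate.
#' @param ... unused.
#' @export
simulate.seqvol_env <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  generate_dataset(object, nsim, seed)
}

#' @export
print.seqvol_seq <- function(x, ...) {
  cat("<seqvol sequence> ", x$structure, ", T = ", length(x$x),
      ", ", sum(x$change_flags[, 1L]), " change point(s)\n", sep = "")
  invisible(x)
}

#' @export
plot.seqvol_seq <- function(x, ...) {
  T_ <- length(x$x)
  plot(seq_len(T_), x$x, pch = 16, cex = 0.4, col = "grey40",
       xlab = "time step", ylab = "observation / latent probability",
       ylim = c(0, 1), ...)
  for (j in seq_len(ncol(x$latents))) {
    lines(seq_len(T_), x$latents[, j], col = j + 1, lwd = 1.5)
  }
  legend("topright", legend = colnames(x$latents), col = seq_len(ncol(x$latents)) + 1,
         lwd = 1.5, bty = "n", cex = 0.8)
  invisible(x)
}

#' Generate sequences with change points locked at given time steps
#'
#' All sequences share the same change-point times (useful for averaging
#' agent behaviour around changes); the latent values drawn at those times
#' differ across sequences. Times are 0-based (t = 0 is the first
#' observation, which carries the initial draw and is never a change point),
#' so valid locked times lie in \[1, T-1\].
#'
#' @inheritParams generate_dataset
#' @param locked_times strictly increasing integer vector of 0-based change
#'   times; may be empty.
#' @return list of \code{"seqvol_seq"} objects.
#' @export
generate_locked_batch <- function(config, locked_times, n, seed) {
  stopifnot(inherits(config, "seqvol_env"))
  locked_times <- as.integer(locked_times)
  if (length(locked_times) > 0L) {
    if (any(locked_times < 1L) || any(locked_times >= config$length)) {
      stop("locked times must lie in [1, T-1] (0-based)")
    }
    if (is.unsorted(locked_times, strictly = TRUE)) {
      stop("locked times must be strictly increasing")
    }
  }
  flags <- rep(FALSE, config$length)
  flags[locked_times + 1L] <- TRUE
  nl <- n_latents(config$structure)
  lapply(seq_len(n), function(i) {
    with_seed(derive_seed(seed, i), {
      lat <- vapply(seq_len(nl), function(j) latents_from_flags(flags),
                    numeric(config$length))
      fl <- matrix(flags, nrow = config$length, ncol = nl)
      x <- sample_observations(config$structure, lat)
      make_sequence(config, x, lat, fl)
    })
  })
}

#' Streak probe set for higher-level change inference
#'
#' Builds the probe material used to test whether an agent transfers the
#' suspicion of a change from one bigram probability to the other. Each
#' probe is a prefix of \code{prefix_length} observations generated from
#' fixed bigram probabilities (no change points): the "observed" bigram has
#' probability \code{observed_prob} (so that a later streak of repetitions
#' is surprising) and the "unobserved" bigram has probability 0.2 or 0.8.
#' The four crossed conditions (observed bigram 0|0 or 1|1, unobserved
#' probability 0.2 or 0.8) each contain \code{n_per_condition} sequences.
#' After the prefix, the agent is queried with the unobserved-bigram context
#' (input 0 if the unobserved bigram is 0|0, else 1), presented with m
#' repetitions of the observed value, and queried again; see
#' \code{\link{streak_transfer_experiment}}.
#'
#' @param seed integer seed.
#' @param n_per_condition sequences per crossed condition (default 100,
#'   i.e. 400 total).
#' @param prefix_length prefix length in observations (default 74).
#' @param streak_range integer vector of streak lengths m (default 2:75).
#' @param observed_prob generative probability of the observed bigram
#'   (default 0.2).
#' @param unobserved_probs the two probabilities crossed for the unobserved
#'   bigram (default c(0.2, 0.8)).
#' @return object of class \code{"probe_set"}: list of condition records,
#'   each with fields \code{observed_bigram}, \code{unobserved_prob},
#'   \code{sequences} (list of integer vectors), \code{query_value},
#'   \code{streak_value}; plus attribute \code{streak_range}.
#' @export
generate_streak_probes <- function(seed, n_per_condition = 100L,
                                   prefix_length = 74L,
                                   streak_range = 2:75,
                                   observed_prob = 0.2,
                                   unobserved_probs = c(0.2, 0.8)) {
  streak_range <- as.integer(streak_range)
  if (any(streak_range < 2L) || any(streak_range > 75L)) {
    stop("streak lengths must lie within [2, 75]")
  }
  conds <- expand.grid(observed_bigram = c("0|0", "1|1"),
                       unobserved_prob = unobserved_probs,
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(conds))
  k <- 0L
  for (i in seq_len(nrow(conds))) {
    ob <- conds$observed_bigram[i]
    up <- conds$unobserved_prob[i]
    if (ob == "1|1") {
      p00 <- up; p11 <- observed_prob
    } else {
      p00 <- observed_prob; p11 <- up
    }
    seqs <- lapply(seq_len(n_per_condition), function(j) {
      with_seed(derive_seed(seed, i * 100000L + j), {
        lat <- cbind(rep(p00, prefix_length), rep(p11, prefix_length))
        sample_observations("bigram_independent", lat)
      })
    })
    k <- k + 1L
    out[[k]] <- list(observed_bigram = ob,
                     unobserved_prob = up,
                     sequences = seqs,
                     query_value = if (ob == "1|1") 0L else 1L,
                     streak_value = if (ob == "1|1") 1L else 0L)
  }
  structure(out, streak_range = streak_range, class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  n <- sum(vapply(x, function(c) length(c$sequences), integer(1)))
  cat("<streak probe set> ", length(x), " conditions, ", n, " sequences, m in [",
      min(attr(x, "streak_range")), ", ", max(attr(x, "streak_range")), "]\n",
      sep = "")
  invisible(x)
}

#' Write / read sequences as CSV
#'
#' Columnar text serialisation: columns \code{seq} (sequence id), \code{t}
#' (0-based time step), \code{x}, one column per latent probability and one
#' logical flag column per latent marking change points.
#'
#' @param seqs list of \code{"seqvol_seq"} objects.
#' @param path file path.
#' @export
write_sequences_csv <- function(seqs, path) {
  tabs <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    d <- data.frame(seq = i, t = seq_along(s$x) - 1L, x = s$x)
    lat <- as.data.frame(s$latents)
    fl <- as.data.frame(s$change_flags)
    names(fl) <- paste0("change_", names(fl))
    cbind(d, lat, fl)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequences_csv
#' @param structure,change_prob environment fields recorded on the restored
#'   sequences.
#' @export
read_sequences_csv <- function(path, structure, change_prob = 1 / 75) {
  d <- utils::read.csv(path)
  cfg <- env_config(structure, change_prob, length = sum(d$seq == d$seq[1L]))
  ln <- latent_names(structure)
  lapply(split(d, d$seq), function(ds) {
    lat <- as.matrix(ds[, ln, drop = FALSE])
    fl <- as.matrix(ds[, paste0("change_", ln), drop = FALSE])
    rownames(lat) <- NULL
    rownames(fl) <- NULL
    make_sequence(cfg, as.integer(ds$x), lat, fl)
  })
}

#' Write a dataset manifest
#'
#' Records the generating configuration, seed and file inventory (with MD5
#' checksums) as YAML next to a serialised dataset.
#'
#' @param path manifest file path.
#' @param config environment configuration.
#' @param seed dataset seed.
#' @param n number of sequences.
#' @param files character vector of data files covered by the manifest.
#' @export
write_dataset_manifest <- function(path, config, seed, n, files = character()) {
  manifest <- list(structure = config$structure,
                   change_prob = config$change_prob,
                   length = config$length,
                   seed = as.integer(seed),
                   n_sequences = as.integer(n),
                   files = lapply(files, function(f) {
                     list(path = f, md5 = unname(tools::md5sum(f)))
                   }))
  yaml::write_yaml(manifest, path)
  invisible(path)
}
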