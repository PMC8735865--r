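# Independent brute-force oracle for the ideal observer: enumerates every
# change-point configuration, weighs it by its prior probability, and
# computes segment likelihoods by direct grid sums. Shares no code with the
# forward filter.

bern_lik <- function(v, x) if (x == 1L) v else 1 - v

# Posterior-weighted likelihood and mean of one segment of observations
# under a discrete uniform prior over grid values v. `liks` is a vector of
# per-value products of Bernoulli likelihoods.
segment_stats <- function(v, liks) {
  w <- mean(liks)
  m <- if (w > 0) sum(liks * v) / sum(liks) else 0.5
  list(w = w, m = m)
}

# Prediction of observation k+1 given x[1..k] in the unigram environment,
# by enumeration over change flags at steps 2..k+1.
enum_predict_unigram <- function(x, k, pc, n_bins = 20L) {
  v <- (seq_len(n_bins) - 0.5) / n_bins
  if (k == 0L) return(0.5)
  num <- 0; den <- 0
  for (code in 0:(2^k - 1L)) {
    flags <- as.integer(intToBits(code))[seq_len(k)]  # change at steps 2..k+1
    prior <- prod(ifelse(flags == 1L, pc, 1 - pc))
    seg_id <- cumsum(c(1L, flags))                     # segment of steps 1..k+1
    w <- 1; m_last <- 0.5
    for (s in unique(seg_id)) {
      steps <- which(seg_id == s)
      obs_steps <- steps[steps <= k]
      if (length(obs_steps) == 0L) { m <- 0.5; ws <- 1 }
      else {
        liks <- rep(1, n_bins)
        for (t in obs_steps) liks <- liks * bern_lik(v, x[t])
        st <- segment_stats(v, liks)
        ws <- st$w; m <- st$m
      }
      w <- w * ws
      if ((k + 1L) %in% steps) m_last <- m
    }
    num <- num + prior * w * m_last
    den <- den + prior * w
  }
  num / den
}

# Same for the bigram environments. prev[t] is the observation preceding
# step t (0 before the first). Change flags are enumerated per latent
# (independent) or shared (coupled).
enum_predict_bigram <- function(x, k, pc, coupled, n_bins = 20L) {
  v <- (seq_len(n_bins) - 0.5) / n_bins
  prev <- c(0L, x)[seq_len(k + 1L)]
  if (k == 0L) return(0.5)
  lat_lik_mean <- function(flags, latent) {
    # latent 1: p(0|0) over steps with prev == 0 (success = observing 0);
    # latent 2: p(1|1) over steps with prev == 1 (success = observing 1)
    seg_id <- cumsum(c(1L, flags))
    w <- 1; m_last <- 0.5
    for (s in unique(seg_id)) {
      steps <- which(seg_id == s)
      obs_steps <- steps[steps <= k]
      obs_steps <- obs_steps[prev[obs_steps] == (latent - 1L)]
      if (length(obs_steps) == 0L) { ws <- 1; m <- 0.5 }
      else {
        liks <- rep(1, n_bins)
        for (t in obs_steps) {
          succ <- if (latent == 1L) 1L - x[t] else x[t]
          liks <- liks * bern_lik(v, succ)
        }
        st <- segment_stats(v, liks)
        ws <- st$w; m <- st$m
      }
      w <- w * ws
      if ((k + 1L) %in% steps) m_last <- m
    }
    list(w = w, m = m_last)
  }
  configs <- 0:(2^k - 1L)
  num <- 0; den <- 0
  for (c1 in configs) {
    f1 <- as.integer(intToBits(c1))[seq_len(k)]
    p1 <- prod(ifelse(f1 == 1L, pc, 1 - pc))
    l1 <- lat_lik_mean(f1, 1L)
    if (coupled) {
      l2 <- lat_lik_mean(f1, 2L)
      pred <- if (prev[k + 1L] == 1L) l2$m else 1 - l1$m
      num <- num + p1 * l1$w * l2$w * pred
      den <- den + p1 * l1$w * l2$w
    } else {
      for (c2 in configs) {
        f2 <- as.integer(intToBits(c2))[seq_len(k)]
        p2 <- prod(ifelse(f2 == 1L, pc, 1 - pc))
        l2 <- lat_lik_mean(f2, 2L)
        pred <- if (prev[k + 1L] == 1L) l2$m else 1 - l1$m
        num <- num + p1 * p2 * l1$w * l2$w * pred
        den <- den + p1 * p2 * l1$w * l2$w
      }
    }
  }
  num / den
}

# Central finite-difference gradient of the network minibatch loss with
# respect to every parameter entry.
numeric_net_grad <- function(params, X, eps = 1e-5) {
  out <- list()
  for (nm in setdiff(names(params), c("arch", "n_units"))) {
    g <- params[[nm]]
    g[] <- NA_real_
    for (i in seq_along(params[[nm]])) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      g[i] <- (seqvol:::cpp_loss_grad(pp, X)$loss -
                 seqvol:::cpp_loss_grad(pm, X)$loss) / (2 * eps)
    }
    out[[nm]] <- g
  }
  out
}
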