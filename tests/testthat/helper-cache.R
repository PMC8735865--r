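# Session-level cache for expensive shared artifacts (datasets, trained
# networks, ideal-observer traces) so that independent test files reuse
# them instead of retraining.

.seqvol_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .seqvol_test_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .seqvol_test_cache)
  }
  get(key, envir = .seqvol_test_cache, inherits = FALSE)
}

unigram_env <- function() env_config("unigram")
bigram_env <- function() env_config("bigram_independent")

unigram_train <- function() {
  cached("unigram_train", generate_dataset(unigram_env(), 3200L, seed = 11L))
}
unigram_test <- function() {
  cached("unigram_test", generate_dataset(unigram_env(), 250L, seed = 99L))
}
bigram_train <- function() {
  cached("bigram_train", generate_dataset(bigram_env(), 8000L, seed = 21L))
}
bigram_test <- function() {
  cached("bigram_test", generate_dataset(bigram_env(), 250L, seed = 98L))
}

unigram_refs <- function() {
  cached("unigram_refs", {
    opt <- optimal_agent("unigram")
    list(L_opt = agent_log_lik(opt, unigram_test()),
         L_ch = chance_log_lik(unigram_test()))
  })
}
bigram_refs <- function() {
  cached("bigram_refs", {
    opt <- optimal_agent("bigram_independent")
    list(L_opt = agent_log_lik(opt, bigram_test()),
         L_ch = chance_log_lik(bigram_test()))
  })
}

gated_unigram_nets <- function(n = 5L) {
  cached(paste0("gated_unigram_", n),
         lapply(seq_len(n), function(s) fit_rnn("gated", unigram_train(),
                                                seed = s)))
}
no_gating_unigram_net <- function() {
  cached("no_gating_unigram",
         fit_rnn("no_gating", unigram_train(), seed = 1L))
}
bigram_nets <- function(arch, n = 5L) {
  cached(paste0("bigram_", arch, "_", n),
         lapply(seq_len(n), function(s) fit_rnn(arch, bigram_train(),
                                                seed = s)))
}

# readout fitting material (unigram)
unigram_ro_train <- function() {
  cached("unigram_ro_train", generate_dataset(unigram_env(), 200L, seed = 301L))
}
unigram_ro_test <- function() {
  cached("unigram_ro_test", generate_dataset(unigram_env(), 50L, seed = 302L))
}
unigram_opt_traces <- function(which = c("train", "test")) {
  which <- match.arg(which)
  cached(paste0("unigram_opt_traces_", which), {
    opt <- optimal_agent("unigram")
    seqs <- if (which == "train") unigram_ro_train() else unigram_ro_test()
    lapply(seqs, function(s) predict(opt, s))
  })
}
net_hidden <- function(net, seqs, key) {
  cached(key, do.call(rbind, lapply(seqs, function(s) predict(net, s)$hidden)))
}
precision_readouts <- function() {
  cached("precision_readouts", {
    psi <- unlist(lapply(unigram_opt_traces("train"), trace_psi_steps))
    lapply(seq_along(gated_unigram_nets()), function(i) {
      net <- gated_unigram_nets()[[i]]
      H <- net_hidden(net, unigram_ro_train(), paste0("H_gated_train_", i))
      fit_readout(H, psi, label = "psi")
    })
  })
}

# readout material (bigram)
bigram_ro_train <- function() {
  cached("bigram_ro_train", generate_dataset(bigram_env(), 200L, seed = 401L))
}
bigram_ro_test <- function() {
  cached("bigram_ro_test", generate_dataset(bigram_env(), 50L, seed = 402L))
}
bigram_opt_traces <- function(which = c("train", "test")) {
  which <- match.arg(which)
  cached(paste0("bigram_opt_traces_", which), {
    opt <- optimal_agent("bigram_independent")
    seqs <- if (which == "train") bigram_ro_train() else bigram_ro_test()
    lapply(seqs, function(s) predict(opt, s))
  })
}
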