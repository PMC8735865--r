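#' Experiment presets
#'
#' Ready-made experiment configurations mirroring the study's main
#' analyses, at full scale by default. The \code{scale} factor shrinks
#' replicate counts and dataset sizes proportionally (never the sequence
#' length or network sizes, which would change the science).
#'
#' Available presets:
#' \describe{
#'   \item{performance-unigram}{four network architectures plus the four
#'     heuristics, trained on 160 minibatches of 20 unigram sequences,
#'     scored on 1000 test sequences (percent of optimal).}
#'   \item{performance-bigram}{same with 400 minibatches in the changing
#'     bigram environment (independent change points).}
#'   \item{learning-rate}{effective-learning-rate curves of the optimal
#'     agent, a fitted delta-rule and trained gated networks on 10,000
#'     change-point-locked unigram sequences.}
#'   \item{readout-precision}{precision readouts of gated unigram networks:
#'     900 fitting and 100 held-out sequences, learning-rate correlation on
#'     300 sequences.}
#'   \item{bigram-readout}{bigram estimate (log-odds) and precision
#'     readouts of gated bigram networks.}
#'   \item{perturbation}{constrained activity perturbations at 1000 probe
#'     points over 300 sequences, per architecture.}
#'   \item{higher-level}{streak-transfer probes of networks trained with
#'     coupled vs independent change points (400 probe sequences).}
#'   \item{complexity}{performance versus network size on a logarithmic
#'     grid between 1 and 45 units, with a power-law fit for the
#'     architecture without gating.}
#' }
#'
#' @param name preset name.
#' @param scale positive scale factor for replicates and dataset sizes.
#' @param seed global experiment seed.
#' @return object of class \code{"experiment_config"}.
#' @export
preset <- function(name = c("performance-unigram", "performance-bigram",
                            "learning-rate", "readout-precision",
                            "bigram-readout", "perturbation", "higher-level",
                            "complexity"),
                   scale = 1, seed = 1L) {
  name <- match.arg(name)
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0) {
    stop("`scale` must be a positive number")
  }
  sc <- function(x) max(1L, as.integer(ceiling(x * scale)))
  base <- switch(
    name,
    "performance-unigram" = list(
      structure = "unigram", analysis = "performance",
      archs = c("gated", "no_gating", "no_lateral", "frozen_recurrence"),
      heuristics = c("delta_unigram", "leaky_unigram"),
      replicates = sc(20L), train_minibatches = sc(160L),
      test_sequences = sc(1000L)),
    "performance-bigram" = list(
      structure = "bigram_independent", analysis = "performance",
      archs = c("gated", "no_gating", "no_lateral", "frozen_recurrence"),
      heuristics = c("delta_unigram", "leaky_unigram",
                     "delta_bigram", "leaky_bigram"),
      replicates = sc(20L), train_minibatches = sc(400L),
      test_sequences = sc(1000L)),
    "learning-rate" = list(
      structure = "unigram", analysis = "learning_rate",
      archs = "gated", replicates = sc(20L), train_minibatches = sc(160L),
      locked_sequences = sc(10000L), locked_times = c(100L, 200L, 300L)),
    "readout-precision" = list(
      structure = "unigram", analysis = "readout",
      archs = "gated", replicates = sc(20L), train_minibatches = sc(160L),
      readout_train_sequences = sc(900L), readout_test_sequences = sc(100L),
      correlation_sequences = sc(300L),
      targets = "psi"),
    "bigram-readout" = list(
      structure = "bigram_independent", analysis = "readout",
      archs = "gated", replicates = sc(20L), train_minibatches = sc(400L),
      readout_train_sequences = sc(900L), readout_test_sequences = sc(100L),
      correlation_sequences = sc(300L),
      targets = c("logodds", "psi")),
    "perturbation" = list(
      structure = "unigram", analysis = "perturbation",
      archs = c("gated", "no_gating", "no_lateral", "frozen_recurrence"),
      replicates = sc(20L), train_minibatches = sc(160L),
      readout_train_sequences = sc(900L),
      probe_sequences = sc(300L), probe_points = sc(1000L)),
    "higher-level" = list(
      structure = "bigram_coupled", analysis = "higher_level",
      archs = c("gated", "no_gating", "no_lateral", "frozen_recurrence"),
      replicates = sc(20L), train_minibatches = sc(400L),
      probes_per_condition = sc(100L)),
    "complexity" = list(
      structure = "unigram", analysis = "complexity",
      archs = c("gated", "no_gating"),
      n_grid = unique(round(exp(seq(log(2), log(45), length.out = 8)))),
      replicates = sc(20L), train_minibatches = sc(400L),
      test_sequences = sc(1000L)))
  structure(c(list(name = name, scale = scale, seed = as.integer(seed),
                   n_units = 11L, change_prob = 1 / 75, length = 380L),
              base),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment config> ", x$name, " (scale ", x$scale, ", seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

train_roster <- function(config, train_seqs) {
  agents <- list()
  for (arch in config$archs) {
    for (r in seq_len(config$replicates)) {
      id <- paste0(arch, "_", r)
      agents[[id]] <- fit_rnn(arch, train_seqs, n_units = config$n_units,
                              seed = derive_seed(config$seed, 7000L +
                                                   match(arch, config$archs) *
                                                   100L + r))
    }
  }
  for (h in config$heuristics %||% character()) {
    parts <- strsplit(h, "_")[[1L]]
    for (r in seq_len(config$replicates)) {
      id <- paste0(h, "_", r)
      agents[[id]] <- fit_heuristic(parts[1L], parts[2L], train_seqs,
                                    seed = derive_seed(config$seed,
                                                       9000L + r))
    }
  }
  agents
}

`%||%` <- function(a, b) if (is.null(a)) b else a

agent_label <- function(id) sub("_[0-9]+$", "", id)

#' Run a preset experiment
#'
#' Generates the datasets, trains the rostered agents, runs the preset's
#' analysis and writes tidy CSV tables plus a JSON run manifest (config,
#' seeds, file inventory with MD5 checksums) into \code{out_dir}.
#' Re-running an identical configuration reproduces identical outputs.
#'
#' @param config an \code{\link{preset}} configuration.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly (class \code{"run_manifest"}).
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  env <- env_config(config$structure, config$change_prob, config$length)
  files <- character(0)
  emit <- function(df, fname) {
    path <- file.path(out_dir, fname)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  train_seqs <- if (!is.null(config$train_minibatches)) {
    generate_dataset(env, config$train_minibatches * 20L,
                     derive_seed(config$seed, 1L))
  }

  if (config$analysis == "performance") {
    test <- generate_dataset(env, config$test_sequences,
                             derive_seed(config$seed, 2L))
    opt <- optimal_agent(config$structure, config$change_prob)
    L_opt <- agent_log_lik(opt, test)
    L_ch <- chance_log_lik(test)
    agents <- train_roster(config, train_seqs)
    tab <- data.frame(agent = names(agents),
                      type = vapply(names(agents), agent_label, character(1)),
                      log_lik = vapply(agents, agent_log_lik, numeric(1),
                                       sequences = test),
                      row.names = NULL)
    tab$percent_optimal <- percent_optimal(tab$log_lik, L_opt, L_ch)
    emit(tab, "performance.csv")
  } else if (config$analysis == "learning_rate") {
    locked <- generate_locked_batch(env, config$locked_times,
                                    config$locked_sequences,
                                    derive_seed(config$seed, 3L))
    agents <- train_roster(config, train_seqs)
    agents[["optimal"]] <- optimal_agent(config$structure, config$change_prob)
    agents[["delta_unigram_ref"]] <- fit_heuristic("delta", "unigram",
                                                   train_seqs,
                                                   seed = config$seed)
    curves <- lapply(agents, function(a) {
      alphas <- vapply(locked, function(s) {
        lr <- effective_learning_rate(predict(a, s), s$x)
        ifelse(lr$valid, lr$alpha, NA_real_)
      }, numeric(env$length))
      rowMeans(alphas, na.rm = TRUE)
    })
    tab <- data.frame(t = rep(seq_len(env$length) - 1L, length(curves)),
                      agent = rep(names(curves), each = env$length),
                      alpha = unlist(curves, use.names = FALSE))
    emit(tab, "learning_rate.csv")
  } else if (config$analysis == "readout") {
    agents <- train_roster(config, train_seqs)
    ro_train <- generate_dataset(env, config$readout_train_sequences,
                                 derive_seed(config$seed, 4L))
    ro_test <- generate_dataset(env, config$readout_test_sequences,
                                derive_seed(config$seed, 5L))
    opt <- optimal_agent(config$structure, config$change_prob)
    tab <- readout_table(agents, opt, ro_train, ro_test, config$targets)
    emit(tab, "readout.csv")
  } else if (config$analysis == "perturbation") {
    agents <- train_roster(config, train_seqs)
    ro_train <- generate_dataset(env, config$readout_train_sequences,
                                 derive_seed(config$seed, 4L))
    probes <- generate_dataset(env, config$probe_sequences,
                               derive_seed(config$seed, 6L))
    opt <- optimal_agent(config$structure, config$change_prob)
    tmats <- lapply(ro_train, function(s) predict(opt, s))
    psi <- unlist(lapply(tmats, trace_psi_steps))
    rows <- list()
    for (id in names(agents)) {
      net <- agents[[id]]
      H <- do.call(rbind, lapply(ro_train, function(s) predict(net, s)$hidden))
      ro <- fit_readout(H, psi, label = "psi")
      pe <- perturbation_experiment(net, ro, probes,
                                    n_probes = config$probe_points,
                                    seed = derive_seed(config$seed,
                                                       match(id, names(agents))))
      rows[[id]] <- data.frame(agent = id, type = agent_label(id),
                               delta = pe$deltas,
                               mean_change = pe$mean_change,
                               intensity = pe$intensity)
    }
    emit(do.call(rbind, rows), "perturbation.csv")
  } else if (config$analysis == "higher_level") {
    env_ind <- env_config("bigram_independent", config$change_prob,
                          config$length)
    train_ind <- generate_dataset(env_ind, config$train_minibatches * 20L,
                                  derive_seed(config$seed, 11L))
    probes <- generate_streak_probes(derive_seed(config$seed, 12L),
                                     n_per_condition = config$probes_per_condition)
    rows <- list()
    for (arch in config$archs) {
      nets_c <- lapply(seq_len(config$replicates), function(r)
        fit_rnn(arch, train_seqs, n_units = config$n_units,
                seed = derive_seed(config$seed, 21000L + r)))
      nets_i <- lapply(seq_len(config$replicates), function(r)
        fit_rnn(arch, train_ind, n_units = config$n_units,
                seed = derive_seed(config$seed, 22000L + r)))
      st <- streak_transfer_experiment(nets_c, nets_i, probes)
      rows[[arch]] <- data.frame(arch = arch,
                                 m = as.integer(names(st$mean_coupled)),
                                 coupled = st$mean_coupled,
                                 independent = st$mean_independent,
                                 p_pooled = st$pooled_test$p_value)
    }
    emit(do.call(rbind, rows), "higher_level.csv")
  } else if (config$analysis == "complexity") {
    rows <- list()
    for (arch in config$archs) {
      sw <- complexity_sweep(arch, env, config$n_grid,
                             replicates = config$replicates,
                             n_train_minibatches = config$train_minibatches,
                             n_test = config$test_sequences,
                             seed = derive_seed(config$seed,
                                                match(arch, config$archs)))
      rows[[arch]] <- cbind(arch = arch, sw$summary)
    }
    tab <- do.call(rbind, rows)
    emit(tab, "complexity.csv")
    ng <- tab[tab$arch == "no_gating" & tab$mean < 100, ]
    if (nrow(ng) >= 3L) {
      pl <- fit_power_law(ng$n_units, ng$mean)
      emit(data.frame(coefficient = pl$coefficient, exponent = pl$exponent,
                      r_squared = pl$r_squared), "power_law.csv")
    }
  }

  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("seqvol")),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(structure(manifest, class = "run_manifest"))
}

# One row per (agent, target, latent): held-out Pearson r of the linear
# readout, plus the precision / learning-rate correlation for psi targets.
readout_table <- function(agents, opt, ro_train, ro_test, targets) {
  opt_train <- lapply(ro_train, function(s) predict(opt, s))
  opt_test <- lapply(ro_test, function(s) predict(opt, s))
  nl <- ncol(opt_train[[1L]]$psi)
  rows <- list()
  for (id in names(agents)) {
    net <- agents[[id]]
    H_train <- do.call(rbind, lapply(ro_train,
                                     function(s) predict(net, s)$hidden))
    H_test <- do.call(rbind, lapply(ro_test,
                                    function(s) predict(net, s)$hidden))
    for (target in targets) {
      getter <- if (target == "psi") trace_psi_steps else trace_logodds_steps
      for (l in seq_len(nl)) {
        y_train <- unlist(lapply(opt_train, getter, latent = l))
        y_test <- unlist(lapply(opt_test, getter, latent = l))
        ro <- fit_readout(H_train, y_train, label = target)
        rows[[length(rows) + 1L]] <-
          data.frame(agent = id, target = target, latent = l,
                     train_r = ro$train_r,
                     test_r = evaluate_readout(ro, H_test, y_test))
      }
    }
  }
  do.call(rbind, rows)
}
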