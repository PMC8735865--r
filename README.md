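# seqvol

Sequence prediction agents for stochastic, changing, and structured binary
environments.

## The problem

Many natural prediction problems reduce to this: observe a binary sequence
one symbol at a time and, at every step, estimate the probability that the
next symbol is a 1. The sequences here are doubly difficult — they are
*stochastic* (observations are drawn from latent probabilities) and
*changing* (at hidden change points, occurring with probability
p<sub>c</sub> = 1/75 per step, each latent probability is redrawn uniformly
on [0,1]). Three environments add increasing latent structure:

* **changing unigram** — a single base rate p(1);
* **changing bigram, independent** — two transition probabilities p(0|0)
  and p(1|1), changing independently;
* **changing bigram, coupled** — the same two probabilities, but their
  change points always coincide, so suspicion of a change in one should
  transfer to the other.

The package is built for computational-neuroscience work on how *simple*
systems can approximate Bayes-optimal prediction in such environments. It
provides, as tested and reusable components:

* the three **environment simulators** (plus change-point-locked batches
  and streak-probe generators for targeted analyses);
* the **ideal observer**: exact Bayesian inference by a hidden-Markov
  forward filter on a 20-bin discretisation of each latent probability;
* four **heuristic agents** (delta-rule / leaky counts × unigram / bigram
  scope) with their single free parameter fitted by SGD;
* four **recurrent network architectures** — a gated (GRU-style) network
  and ablations without gating, without lateral connections, or without
  recurrent weight training — initialised from the published
  hyperparameter table and trained end-to-end by backpropagation through
  time with Adam (compiled core, single CPU);
* the **analysis suite**: percent-of-optimal log likelihood, effective
  learning rate, linear readouts of latent estimates and their precision,
  mutual information, constrained activity perturbations, higher-level
  change-inference probes, complexity scaling with power-law fits, and the
  group statistics used to compare agents.

An agent's score is the log likelihood of its predictions,
L = Σ<sub>t</sub> log[x<sub>t+1</sub> p<sub>t</sub> + (1 −
x<sub>t+1</sub>)(1 − p<sub>t</sub>)], reported as the *percent of optimal
log likelihood*: 0% is chance (constant 0.5), 100% is the ideal observer.

## Worked example

Train one 11-unit gated network in the changing unigram environment and
compare it with the ideal observer and a fitted delta rule:

```r
library(seqvol)
env <- env_config("unigram")          # T = 380, change prob 1/75
train <- generate_dataset(env, 160 * 20, seed = 1)
test  <- generate_dataset(env, 250, seed = 2)

net <- fit_rnn("gated", train, seed = 1)
net
#> <recurrent network> gated, N = 11, unigram hyperparameters, trained
#>   160 minibatches, final training loss 0.546463

opt <- optimal_agent("unigram")
report <- performance_report(
  L = sapply(list(net, fit_heuristic("delta", "unigram", train, seed = 1)),
             agent_log_lik, sequences = test),
  L_optimal = agent_log_lik(opt, test),
  L_chance  = chance_log_lik(test))
round(report$percent, 1)
#> [1] 98.9 90.0
```

The gated network scores 98.9% of the ideal observer's log likelihood —
within about a point of Bayes-optimal — while the classic delta rule
plateaus near 90%: its fixed learning rate cannot adapt to change points.
The adaptation itself is measurable:

```r
s <- test[[1]]
tr <- predict(net, s)                  # predictions + hidden states
lr <- effective_learning_rate(tr, s$x)
round(mean(lr$alpha[lr$valid]), 3)
#> [1] 0.054
```

The effective learning rate (prediction update / prediction error) of the
trained network is not constant: it peaks just after change points, like
the ideal observer's, and its moment-by-moment value can be predicted from
a linear readout of the hidden state that tracks the observer's posterior
precision (see `fit_readout()`, `perturbation_experiment()` and the
methods vignette in `vignettes/seqvol-methods.Rmd`).

Larger experiments are packaged as presets:

```r
run_experiment(preset("performance-bigram", scale = 0.25, seed = 1), "out/")
```

writes tidy CSV tables plus a JSON manifest with checksums; `scale`
shrinks replicate counts and dataset sizes, never the science (sequence
length, architectures, training protocol).

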