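---
title: "Predicting binary sequences in changing environments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting binary sequences in changing environments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqvol)
```

## The prediction problem

An agent observes a binary sequence $x_0, x_1, \dots, x_{T-1}$ one symbol at
a time and, after each observation, reports $p_t$, its estimate of
$P(x_{t+1} = 1 \mid x_0, \dots, x_t)$. The agent's score is the sequence log
likelihood

$$L = \sum_{t} \log\left[x_{t+1} p_t + (1 - x_{t+1})(1 - p_t)\right],$$

the negative binary cross-entropy of its predictions. This is a
self-supervised criterion: the training signal is the discrepancy between
the prediction and the next observation, with no external labels.

What makes the problem hard is that the generative probabilities are
*latent and unstable*. In the **changing unigram environment**, a single
base rate $p(1)$ governs the observations; at every step it is replaced,
with probability $p_c$, by a fresh draw from $\mathrm{Uniform}[0,1]$ (a
*change point*). The **changing bigram environments** instead use two
transition probabilities, $p(0|0)$ and $p(1|1)$ (the probability of
repeating the previous symbol), each evolving by the same
change-point process — with independent change points in one variant and
*coupled* (simultaneous) change points in the other. Defaults follow the
study conditions throughout: $T = 380$ observations per sequence and
$p_c = 1/75$, values taken from the experimental literature on human
sequence learning. The observation preceding a sequence is defined to be 0,
so the first bigram prediction conditions on a 0.

Randomness plus change points create a stability–flexibility dilemma:
integrating many observations gives stable estimates of a stationary
probability, but after a change the old observations are misleading and the
estimate should be rebuilt quickly. The coupled-bigram environment adds a
second, higher level of structure: evidence that *one* transition
probability has changed is also evidence that the *other* one has.

## The ideal observer

The Bayes-optimal predictor inverts the generative process. The package
implements it as a hidden-Markov forward filter over a discretised latent
space: each probability axis is cut into 20 equal-width bins represented by
their centres $(k + 0.5)/20$, so the unigram observer tracks 20 posterior
masses and the bigram observers a $20 \times 20$ joint grid over
$(p(0|0), p(1|1))$. Each step applies

* the **transition kernel** — with probability $p_c$ the latent is redrawn
  uniformly, so mass is mixed with the uniform distribution (independently
  per axis, or jointly when change points are coupled), and
* the **Bernoulli likelihood** of the new observation (selected by the
  previous observation in the bigram case), followed by renormalisation.

The emitted prediction is the mean of the predictive posterior over the
relevant probability. Filtering is done in linear space with per-step
renormalisation: with at most 400 cells and bin values strictly inside
$(0,1)$, no underflow is possible, and mass normalisation is maintained to
$10^{-12}$ per step (tested). The filter is verified, for short sequences,
against a brute-force oracle that enumerates every change-point
configuration and integrates each segment on the grid directly.

Two summaries of the posterior matter for the analyses: the posterior mean
(reported as log odds for the bigram readouts) and the **log precision**
$\psi_t = -\log \sigma_t$, where $\sigma_t$ is the SD of the predictive
posterior over the latent probability. Natural logarithms are used
throughout. A strict point-mass posterior has $\sigma = 0$ and raises an
explicit error rather than returning an infinite $\psi$; it cannot arise
from the filter itself.

### Trace conventions

All agents return prediction traces of length $T + 1$: entry $k$ is the
prediction for the $k$-th observation given its predecessors, so entry 1 is
the data-free prior prediction (0.5 for the observer and heuristics, the
zero-state output for a network) and the last entry is emitted after the
final observation. The log likelihood scores entries $2 \dots T$, i.e. one
term per observation from the second onwards — exactly the pairs scored by
the self-supervised objective — so chance level (constant 0.5) is
$-(T-1)\log 2$ per sequence. Prediction performance is reported as the
percent of optimal log likelihood,
$(L - L_{\mathrm{chance}})/(L_{\mathrm{optimal}} - L_{\mathrm{chance}})
\times 100$, computed on totals over a test set.

## Heuristic agents

Four heuristics provide simple baselines, crossing the estimated variable
(unigram base rate vs the two bigram probabilities) with the update rule:

* **delta rule** (Rescorla–Wagner): $\hat p \leftarrow \hat p +
  \alpha (x - \hat p)$, initialised at 0.5;
* **leaky counts**: event counts decay by $\alpha$ at each update and the
  estimate is the Laplace ratio $(n_1 + 1)/(n_1 + n_0 + 2)$ — the mean of
  an approximate Beta posterior.

Bigram variants maintain both conditional estimates and update only the one
whose context occurred. Estimate updates consume observed transition pairs
$(x_t, x_{t+1})$ only; the first observation, whose predecessor is the
conventional 0, selects the emitted prediction but updates nothing (the
worked single-step examples in the tests pin this convention down).

The single free parameter $\alpha$ is fitted by minibatch stochastic
gradient descent (step size $3 \times 10^{-3}$, minibatches of 20
sequences, one pass) on the prediction cross-entropy. Gradients are
propagated through the recursion in forward mode, which for a single scalar
parameter is the exact same derivative that backpropagation through time
would produce; they are verified against central finite differences.
$\alpha$ is initialised from $r \sim$ log-uniform on
$[10^{-2.5}, 10^{-0.5}]$ ($\alpha = r$ for the delta rule, $e^{-r}$ for the
leaky rule) and projected to $[10^{-4}, 1 - 10^{-4}]$ (delta) or
$[10^{-4}, 1]$ (leaky) after each step, since the recursion is only defined
on those ranges.

## Recurrent networks

Four small recurrent architectures share a three-layer template: one input
unit carrying the current observation, $N$ recurrent units (default 11),
and one logistic output unit $p = \sigma(w_{hp} \cdot h + b_{hp})$. The
full **gated** architecture is a GRU:

$$
\begin{aligned}
r &= \sigma(W_{xr} x + b_{xr} + W_{hr} h + b_{hr}),\\
z &= \sigma(W_{xz} x + b_{xz} + W_{hz} h + b_{hz}),\\
h' &= z \odot h + (1 - z) \odot
      \tanh\!\left(W_{xh} x + b_{xh} + r \odot (W_{hh} h) + b_{hh}\right),
\end{aligned}
$$

with $h$ initialised to zero. Note two deliberate details: the update gate
$z$ multiplies the *old* state, and the candidate bias $b_{hh}$ sits
outside the reset product (the reset gate scales only the recurrent
drive). The three ablations each remove one mechanism:

* **no gating** — $r \equiv 1$, $z \equiv 0$: a vanilla (Elman) network,
  $h' = \tanh(W_{xh} x + b_{xh} + W_{hh} h + b_{hh})$;
* **no lateral connections** — all recurrent weight matrices are diagonal,
  so units interact only through their own history;
* **frozen recurrence** — full gated dynamics but only the output weights
  and bias are trained (a reservoir).

Since every unit's new state is a convex combination of its old state and a
$\tanh$ output (or a pure $\tanh$), hidden activations remain in $(-1, 1)$
for every architecture and input — a tested invariant.

**Initialisation.** Biases are uniform on $[-1/N, 1/N]$; output weights
normal with SD $1/N$; input weights normal with SD $\sigma_{0,x}$;
recurrent weights normal with SD $\sigma_{0,h}$, mean 0 off-diagonal and
$\mu_{0,h,ii}$ on the diagonal. The per-environment, per-architecture,
per-size values of $(\eta_0, \sigma_{0,x}, \sigma_{0,h}, \mu_{0,h,ii})$
ship as a data file (`load_hyperparameters()`); they are the published
selections of an extensive Bayesian hyperparameter optimisation, which this
package deliberately does not re-run (a tuned random search would be the
replacement if new sizes were ever needed beyond the nearest-size fallback
in log space).

**Training.** A single pass of minibatch Adam (initial step size $\eta_0$,
moment decays 0.9/0.999, $\epsilon = 10^{-8}$ — the standard defaults, not
stated in the source and adopted as such) over the training dataset: 160
minibatches of 20 sequences in the unigram environment, 400 in the bigram
environments. Gradients flow through the full sequence by backpropagation
through time (no truncation, no gradient clipping — a non-finite loss
raises an explicit training failure instead of being clipped away). The
loss is the mean cross-entropy over the $T - 1$ scored steps and the
minibatch; with Adam the overall loss scale is immaterial, but the
convention is fixed for reproducibility. The last prediction of a sequence
has no target and is excluded. Architecture masks are enforced at the
update: frozen-recurrence networks update only $w_{hp}, b_{hp}$;
diagonal-only networks never receive off-diagonal gradient. The BPTT
gradient of every parameter is tested against central finite differences,
and the compiled forward pass against an independent pure-R
single-step implementation.

## Analyses

**Effective learning rate.** The update normalised by the prediction
error, $\alpha_{t+1} = (p_{t+1} - p_t)/(x_{t+1} - p_t)$, with the first
update referenced to 0.5. Steps with $|x - p| < 10^{-6}$ are masked as
degenerate and excluded from averages (the source is silent on this
corner; the threshold is far below any behaviourally meaningful error).
For a delta-rule agent the ratio is identically $\alpha$; for adaptive
agents it rises transiently after change points, which the locked
change-point generator (`generate_locked_batch()`) makes visible by
aligning changes across sequences.

**Linear readouts.** Ordinary least squares with intercept from the $N$
hidden activations to an optimal-observer quantity ($\psi_t$ in the
unigram environment; log odds of the posterior mean and $\psi$ of each
bigram probability in the bigram environment), fitted on one set of
sequences and evaluated as a Pearson correlation on held-out sequences.
The hidden state after observation $t$ is paired with the observer
quantity conditioned on the same observations; the "subsequent" learning
rate paired with $\psi_t$ is strictly the one at $t+1$.

**Mutual information.** The estimator is a plug-in on 32 × 32
equal-frequency bins, in nats (the source does not specify an estimator,
so only orderings — not exact MI values — are treated as reproducible;
the estimator's independence bias is below $(\text{bins}-1)^2 / 2n$).

**Perturbation experiment.** To test whether represented precision
*causally* drives the learning rate, a random perturbation $q$ is added to
the hidden state under three constraints: $q \cdot w_{hp} = 0$ (the
prediction, and hence the next prediction error, is untouched),
$q \cdot w_{h\psi} = \delta$ (a controlled change in read precision), and
$\|q\| = c$ (constant intensity). The construction projects $w_{h\psi}$
into the null space of $w_{hp}$, scales it to produce $\delta$, and fills
the residual norm with a random direction orthogonal to both; all three
constraints hold to $10^{-10}$ by construction (tested, including against
the minimum-norm solution of the constraint system). The source prints
neither $c$ nor the $\delta$ levels, so the defaults are explicit and
recorded in the output: $c = 0.1 \times$ the median hidden-state norm at
the probe points, five $\delta$ levels spanning $\pm 1$ SD of the read
precision, probe times drawn from $t \in [10, T-2]$ to skip the initial
transient.

**Higher-level inference probe.** 400 prefix sequences (74 observations;
observed bigram at probability 0.2, unobserved at 0.2 or 0.8, two
observed-bigram identities, 100 sequences per crossed condition) are each
followed by a query of the unobserved bigram, a streak of $m$ repetitions
of the observed value ($m = 2 \dots 75$), and a second query; the query
observations are part of the input stream, matching the "prediction
following the 0 just before/after the streak" construction. The statistic
is the mean $|p_{\mathrm{after}} - p_{\mathrm{before}}|$, compared between
agents trained with coupled vs independent change points (one-tailed Welch
test): only an agent that has internalised the coupling should reset its
belief about the *unobserved* bigram after a surprising streak of the
observed one.

**Complexity scaling.** Networks are trained across a logarithmic grid of
sizes with nearest-size hyperparameters, and the distance to optimality of
the ungated networks is summarised by the power law
$(100 - p) = c (1/N)^a$, fitted by least squares on
$(\log N, \log(100 - p))$.

**Statistics.** Group comparisons use Welch's two-independent-samples
t-test (two- or one-sided), the paired one-sided t-test (with an explicit
degenerate flag when differences have zero variance), and the interaction
F-test of a balanced 2 × 2 design; confidence intervals for group means
are Student-t over replicate agents.

## The synthetic generators and what the tests show

All data in this package are synthetic by design — the scientific object
*is* the generative environment, so the generators are first-class, tested
code rather than fixtures. They emulate exactly the three stated
generative processes (uniform redraws at geometric change times, Bernoulli
emissions, the conventional previous observation 0) and nothing else: real
behavioural or neural sequences have serial structure, drift and
measurement noise that these processes do not model, so green tests here
certify the computational claims about these environments, not about any
empirical dataset. Reproducibility is enforced by deriving one RNG stream
per sequence from (seed, index), making datasets independent of generation
order; training additionally derives separate streams for initialisation
and data shuffling, so a (seed, dataset) pair fixes the trained network
bit-for-bit.

### Problem sizes

The test suite and the acceptance script replicate the study at desk
scale, chosen once: 5 replicate networks per architecture (instead of 20),
250 test sequences (instead of 1000), 200 readout-fitting and 50
readout-evaluation sequences (instead of 900/100), 100–300 sequences for
the correlation analyses, with full-size training datasets (160 or 400
minibatches of 20 sequences) and the full sequence length $T = 380$ —
scaling never touches the sequence length, the architectures or the
training protocol, only replicate counts and evaluation set sizes.
At these sizes the full-scale published confidence intervals widen by
about $\sqrt{20/5}$, which is the tolerance frame used by the acceptance
checks. The full complexity sweep (20 networks at each of ~12 sizes, plus
a 1000-unit vanilla network) is out of desk range; the `complexity` preset
runs a shrunken grid and the tests check the qualitative claim — a gated
network beats an ungated network of matched trained-parameter count.

### Known limitations

* Observations are binary and dependencies are at most one step
  (bigrams); richer alphabets or longer-range structure are out of scope.
* The ideal observer is exact only up to the 20-bin discretisation; its
  posterior SD carries no continuity correction. A finer or
  endpoint-anchored grid changes its log likelihood by a fraction of a
  percent of the chance–optimal span, which propagates into
  percent-of-optimal values of all agents.
* Replicated training at the stated single-pass budget leaves the gated
  networks a few tenths of a percentage point short of their fully
  converged performance (a second pass closes most of it); the package
  reports what the stated protocol produces.
* The LSTM gating variant and the Gaussian-process hyperparameter search
  of the original study are intentionally not implemented.
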