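---
title: "Signal diversity, integrated information, and directed network topology for spontaneous EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal diversity, integrated information, and directed network topology for spontaneous EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What this package computes

`lzphi` implements a battery of spontaneous-EEG measures used in
anesthesia and consciousness research, together with the simulation
machinery needed to study how those measures relate to network topology
without any recorded data. The battery has three families:

1. **Signal diversity and spectral measures** — mean single-channel
   Lempel–Ziv complexity (LZs), amplitude and synchrony coalition entropy
   (ACE, SCE), Welch power spectra, and the spectral exponent (the
   log–log slope of the PSD, fit on 20–40 Hz).
2. **Gaussian-approximation integrated information** — multi-information
   (MI), mutual integrated information (MII), stochastic interaction
   (SI), decoder-based integrated information (Φ\*), and geometric
   integrated information (Φ^G), each partitioned measure evaluated at
   its minimum information partition (MIP) found with Queyranne's
   algorithm.
3. **Directed network topology** — an order-4 multivariate autoregressive
   (MVAR) fit, the directed transfer function (DTF) aggregated over
   0–40 Hz into a weighted digraph, global efficiency (integration),
   directed-weighted Louvain modularity (segregation), mean connection
   strength, and mean absolute pairwise correlation ("mean coherence", an
   estimate of shared noise).

The package also contains a first-order autoregressive network ensemble
(`ar_config()`, `sample_ar_network()`, `simulate_ar()`) and a driver
(`run_model_study()`) that applies the whole battery to each simulated
network, so the relationships between the measures and ground-truth
topology can be mapped under fully known conditions.

# The autoregressive ensemble

Each network has $n = 8$ nodes evolving as
$X_{t+1} = A X_t + \varepsilon_t$. Off-diagonal weights are i.i.d.
$\mathrm{Beta}(\alpha, \beta)$ with $\alpha, \beta$ drawn uniformly from
$[0.001, 10.1)$ once per network, so the ensemble spans near-binary,
uniform, and tightly peaked weight profiles. Each diagonal entry is $r$
times the median of its row's off-diagonal weights, $r \sim U[3, 6]$
(a continuous draw; the midpoint median is used for the even row count).
Innovations are equicorrelated Gaussian: unit variances, all
off-diagonal correlations equal to a single $c \sim U(0, 1)$. Candidate
matrices are rejected until the spectral radius is below one (cap of
10 000 attempts, then an "unrealizable configuration" error); this
rejection is part of the ensemble definition, concentrating accepted
networks on small weights. Simulations run $t = 10\,000$ steps from a
zero state; the first 10% is discarded before any measure is computed, a
burn-in chosen so that the remaining samples are within numerical
distance of the stationary law (the stationary covariance solves the
discrete Lyapunov equation $\Sigma = A \Sigma A^\top + \Sigma_\varepsilon$,
and `stationary_covariance()` provides it as an oracle; tests verify the
simulated covariance converges to it).

The generated series are treated like EEG sampled at 500 Hz: diversity
measures are computed on 2 000-sample segments (the 4-second trial
convention) and averaged, the DTF band is 0–40 Hz, and one covariance
model is fitted on the whole post-burn-in series. Pooling (rather than
averaging per-segment information measures) mirrors the practice of
estimating a single state-space covariance across trials per recording;
per-epoch fitting remains the default for genuinely epoched EEG input,
where nonstationarity across trials is the rule.

# The Gaussian model and the Φ measures

All information measures are computed from a lagged Gaussian model: the
zero-mean Gaussian approximation of $(X_{t-\tau}, X_t)$ with equal-time
covariances $\Sigma_X, \Sigma_Y$ and cross-covariance $\Sigma_{XY}$.
The lag defaults to $\tau = 1$ sample and is recorded with results; no
published convention fixes it, so it is a configurable parameter rather
than a constant. When the stacked $2n \times 2n$ covariance is not
positive definite a ridge is escalated through
$10^{-12} \dots 10^{-6}$ and recorded.

With Gaussian entropies $h(\Sigma) = \tfrac12 \ln((2\pi e)^k |\Sigma|)$:

* **MI** $= \sum_i h(X_i) - h(X)$ — total equal-time correlation.
* **MII** $= I(X_{t-\tau}; X_t) - \sum_k I(M_{k,t-\tau}; M_{k,t})$ — may
  be negative when parts are individually more self-predictive than the
  whole.
* **SI** $= \sum_k H(M_{k,t} \mid M_{k,t-\tau}) - H(X_t \mid X_{t-\tau})
  \ge 0$.
* **Φ\***: the loss of predictive information under a block-factorized
  (mismatched) decoder. The mismatched information $\tilde I(\beta)$ has
  a closed form for Gaussians (obtained by integrating the powered
  decoder against the prior), and Φ\* maximizes it over the scalar
  decoding parameter $\beta$ with one-dimensional search on $[0, 20]$
  (tolerance $10^{-7}$); $0 \le \Phi^* \le I$ by construction, and the
  optimizer is validated against a dense β grid in the tests.
* **Φ^G**: the minimum KL divergence from the fitted model to the
  manifold of models with no cross-block lagged influence. The
  constrained model's regression matrix is block diagonal; its residual
  covariance is moment-matched, which reduces the divergence to
  $\tfrac12(\ln|M(A)| - \ln|\Sigma_E|)$ with $M(A)$ the residual
  covariance under the constrained regression $A$. The minimizer is
  found by a damped fixed-point iteration on the stationarity condition
  $[M(A)^{-1}(A\Sigma_X - \Sigma_{YX})]_{\text{block}} = 0$ — each
  iteration is one linear solve in the free coefficients, with step
  halving whenever the objective would rise — and a BFGS fallback
  guards the rare non-converged case. Tests compare the result against
  an independent Nelder–Mead minimization of the raw joint-Gaussian KL.

**Partition search.** The MIP minimizes the (unnormalized) measure over
bipartitions using Queyranne's pendant-pair algorithm. The algorithm is
exact for symmetric submodular functions; the Φ objectives are not
guaranteed submodular, so the test suite checks equality against
exhaustive bipartition enumeration on random models up to $n = 8$ — in
practice the pendant-pair search finds the exact MIP on these models.
The complex search scores every subset generated by recursive MIP
bipartitioning by that subset's own measure-at-MIP and returns the best;
it is validated against exhaustive subset enumeration for $n \le 6$.

# Diversity measures

Channels are binarized by thresholding the Hilbert envelope at its
epoch mean (constant channels are flagged and excluded). LZs applies
the LZ76 exhaustive-history parse (implemented in C++, validated against
a direct-definition oracle on every binary string up to length 12) to
each channel and normalizes the parse count by the mean count over
$k = 10$ within-sequence shuffles; this surrogate normalization keeps
values near 1 for structureless signals regardless of the ones-density,
and the classical $c \log_2 n / n$ normalization is available behind a
flag. ACE is the entropy of the binary coalition (which channels are
"on" per sample) normalized by the same entropy after independent
within-channel time shuffling; SCE does the same for per-channel phase
synchrony coalitions at a threshold of 0.8 rad (the cited method's
convention; configurable). All surrogate normalizations use $k = 10$
seeded shuffles — enough to bring the normalizer's Monte-Carlo error
well below the between-condition differences of interest at these
sequence lengths.

# Connectivity and topology

The MVAR fit is multivariate least squares at order 4 (an order-selection
helper minimizing AIC/BIC is included). The DTF is
$\gamma^2_{ij}(f) = |H_{ij}(f)|^2 / \sum_m |H_{im}(f)|^2$ with
$H(f) = (I - \sum_k A_k e^{-i 2 \pi f k / f_s})^{-1}$, so each row sums
to one at every frequency. Adjacency aggregates the DTF by the
trapezoidal area under 0–40 Hz **divided by the band width**: the
division keeps weights in $[0, 1]$, which the distance transform
$d = 1 - w$ requires (raw area would exceed one). Global efficiency is
the mean inverse Dijkstra shortest-path distance over ordered pairs,
with absent edges ($w = 0$) at distance one and $w = 1$ clamped to
$10^{-9}$. Modularity is the directed-weighted form
$Q = \tfrac1m \sum_{ij} (w_{ij} - s_i^{out} s_j^{in} / m)\,
\delta(c_i, c_j)$ optimized by a Louvain two-phase heuristic, best of 10
randomized restarts; an exhaustive partition oracle (all set partitions)
validates it on small graphs, including the exact $Q = 0.5$ two-clique
case. By default the diagonal is zeroed before modularity; the model
study instead retains self-connections as self-loops
(`self_loops = TRUE`), the convention of the common brain-connectivity
toolboxes, where self-loop mass enters the strengths and total weight.
The choice matters: with self-loops the modularity of a DTF-derived
adjacency is dominated by how much influence stays on the diagonal, so
it behaves as an (inverse) index of overall coupling rather than a pure
community-structure readout, and its correspondence with the modularity
of the generating weight matrix is weak — the regime the measure
occupies in the empirical literature this package accompanies.

# The synthetic EEG generator

`generate_recording()` produces epoched, rat-like multichannel data from
a small set of knobs: per-channel $1/f^\gamma$ spectrally shaped Gaussian
noise (flat below 1 Hz), a shared broadband driver blended as
$(b + g\,d)/\sqrt{1+g^2}$ so that the zero-lag correlation rises
monotonically with gain $g$, a shared slow oscillation (0.8–2 Hz) that
both gates the broadband amplitude and adds sub-4 Hz power in proportion
to `slow_osc_fraction`, and an optional mixing matrix. Condition presets
place wake at $\gamma = 1.3$ with little slow-wave content and deep
anesthesia (propofol-like) at $\gamma = 3.0$ with strong slow-wave
gating, magnitudes chosen to match the reported range of spontaneous
spectral exponents across states; ketamine-like profiles stay close to
wake. The generator is a statistical emulator: it reproduces the
spectral slopes, coherence levels, and slow-wave bistability that the
measures respond to, but not evoked responses, artifacts, cross-channel
propagation delays, or any biophysics — so passing condition-contrast
tests demonstrates that the pipeline detects the intended signal
features, not that it would reproduce numerical values from recordings.

# Preprocessing conventions

The documented order is rereference → downsample → bandpass → epoch →
subsample. Filtering is a fourth-order Butterworth bandpass (0.5–45 Hz
default) applied forward–backward; zero-phase filtering is chosen
because phase-based measures (SCE) and lagged covariances should not
inherit filter phase distortion. The bipolar reference is implemented as
subtraction of the single anode–cathode difference channel from every
channel. Downsampling applies an eighth-order zero-phase anti-aliasing
low-pass at 80% of the target Nyquist before decimation. Epochs are
non-overlapping with the trailing remainder dropped; when a
stimulus-onset table is supplied, epochs are taken from pre-stimulus
windows (default −5 s to −1 s). Channel/epoch subsampling is uniform
without replacement with the drawn indices recorded. Bad-channel
rejection is manual-list based; an amplitude-threshold helper exists but
is off by default.

# Numerical choices and degenerate inputs

* Covariance ridge ladder $10^{-12}$–$10^{-6}$, recorded in the model.
* Φ\* values are clamped to $[0, I]$ and Φ^G, SI, MI to $[0, \infty)$
  against numerical noise of order $10^{-12}$.
* Queyranne's forced last element is taken without evaluating the
  trivial (whole-set) cut.
* Constant channels: binarization flags them; correlation and contrast
  functions raise errors rather than returning NaN.
* A measure failure inside `run_model_study()` drops that network and
  records its identity instead of failing the study.
* Wilcoxon contrasts report the smaller rank sum as the integer
  statistic `W` (the convention that makes one-signed effects give
  $W = 0$); exact p-values for $\le 25$ untied pairs.
* No multiple-comparison correction by default; Holm is available via
  the `adjust` argument of `measure_correlations()`.

# Problem sizes

The shipped analysis scripts use 300 networks at $t = 10\,000$ steps for
the model study (about ten minutes on one CPU; the Φ^G partition search
dominates) and 8 synthetic subjects × 4 conditions × 8 epochs for the
condition study. These sizes give Spearman correlations a sampling
standard error of about $1/\sqrt{300} \approx 0.06$, small enough to
read the correlation structure while keeping the scripts re-runnable in
one sitting.

# Known limitations

* The Gaussian approximation ignores higher-order structure; on strongly
  nonlinear or heavy-tailed data the Φ measures characterize only the
  second-order dynamics.
* Queyranne's search is exact only for submodular objectives; its
  agreement with exhaustive search is verified empirically on the model
  class used here, not guaranteed in general.
* The directed Louvain heuristic can in principle miss the global
  modularity optimum on larger graphs; restarts mitigate but do not
  eliminate this.
* "Mean coherence" is implemented as the mean absolute zero-lag Pearson
  correlation; the literature sometimes uses spectral coherence under
  the same name, and the two diverge on strongly lagged dynamics.
* PCI-style perturbational complexity is consumed as an external table
  only; the package never computes it.
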