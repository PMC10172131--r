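---
title: "Methods: contrastive joint behavioural and neural embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrastive joint behavioural and neural embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`contrastembed` learns a feature extractor $f$ mapping windows of a
multidimensional time series $s_t$ (typically binned neural activity) into a
low-dimensional space $Z \subseteq \mathbb{R}^E$. Training is contrastive:
for a reference sample $x$, a positive sample $y_+$ and negatives
$y_1,\dots,y_n$, the loss per batch is

$$ L_n \;=\; \mathbb{E}\Big[-\psi(x, y_+) + \log \sum_{i=1}^n e^{\psi(x, y_i)}\Big],
\qquad \psi(x,y) = \varphi\big(f(x), f(y)\big)/\tau, $$

with $\varphi$ either the dot product between unit-normalized features
(embeddings on the hypersphere $S^{E-1}$) or the negative mean squared error
(embeddings in Euclidean space), scaled by a temperature $\tau$. What makes
the method a scientific instrument rather than a generic representation
learner is that the distributions of $y_+$ and $y_i$ are *designed*:
auxiliary variables — continuous behaviour $c_t$, discrete categories $k_t$,
or time itself — define which samples count as "similar", and thereby which
structure the embedding geometry must expose and which it must discard.

Minimizing $L_n$ estimates the log-ratio of the positive and negative
conditionals; its minimizer is characterized up to a linear transformation
of the embedding, which is why independently trained runs can be compared
with a linear-regression $R^2$ ("linear consistency") and why that score is
the practical test of identifiability.

## Sampling distributions

All samplers operate on the set of *valid windows* — time indices whose
full receptive field fits inside the session — and draw from the full
dataset at every optimizer step, never from a pre-drawn minibatch.

* **References and negatives** follow the empirical distribution over valid
  windows. With `uniform_over_category`, a category is drawn uniformly (by
  inverting the cumulative label histogram) and then a member uniformly;
  applying this to both positives and negatives makes the embedding
  invariant to the label.
* **Discrete conditional**: the positive is uniform among samples sharing
  the reference's label.
* **Continuous conditional**: the empirical difference multiset
  $D = \{c_{t+\tau} - c_t\}$ over the configured offsets $\tau \in \Delta$
  is precomputed once per session; a difference $d$ is drawn uniformly from
  $D$ and the positive is the sample whose context is nearest (Euclidean)
  to $c_{\mathrm{ref}} + d$.
* **Delta conditional**: the target context is drawn from
  $\mathcal{N}(c_{\mathrm{ref}}, \delta^2 I)$ followed by the same
  nearest-neighbour lookup. This is the conditional used throughout the
  synthetic benchmark (`delta = 0.1`).
* **Mixed**: the continuous conditional restricted to candidates sharing
  the reference's discrete label.
* **Time conditional**: the positive sits at an offset drawn uniformly from
  $\Delta$. The reference marginal is restricted to indices that admit at
  least one valid offset, so a draw can never strand at the sequence tail.

Design choices where the procedure was open: nearest-neighbour lookups use
the Euclidean norm on the context regardless of the embedding similarity;
ties break to the smallest time index (1-D contexts use a sorted index with
`findInterval`, higher dimensions a blocked brute-force search); the
reference itself is not excluded from positive candidacy (self-positives
have measure zero for continuous contexts); negatives may collide with the
reference or positive index.

Multi-session batches allocate an equal reference quota
$\lceil n/N \rceil$ per session irrespective of session length, draw the
positive's session uniformly, and match the positive within that session
through the shared continuous context (the within-session conditional is
the configured delta/continuous one). Negatives pool an equal quota from
every session, and one encoder per session maps into the common space, so
the embedding becomes invariant to session identity.

## Encoders

Three families, selected by receptive field (samples consumed per output):

* **RF 1** — four dense layers $D \to H \to H \to H/2 \to E$ (bottleneck at
  the third layer).
* **RF 10** — five time-convolutions with kernels (2, 3, 3, 3, 3); the
  middle three carry additive skip connections (identity on channels, input
  cropped to the valid length).
* **RF 40** — a front end concatenating a fixed 2× average-pool downsample
  of the input with a learned kernel-4 stride-2 convolution, directly
  followed (no activation between) by a kernel-3 stride-2 convolution, then
  three kernel-3 skip layers and a final kernel-3 map to $E$.

GELU activations follow every layer but the last; we use the tanh
formulation of GELU with its exact analytic derivative (the erf form is
numerically indistinguishable here and roughly twice as slow in this
implementation). All convolutions are valid (no padding), so the RF-40
stack's intermediate lengths are $40 \to 19 \to 9 \to 7 \to 5 \to 3 \to 1$:
the kernel plan consumes exactly 40 samples. Note that with valid
convolutions the front end emits a 9-sample sequence, not the 10 that a
naive "40 / 4" subsampling count suggests. Weights use fan-in-scaled
uniform initialization, drawn from R's RNG so a seed fixes the model
exactly. With cosine similarity the output is L2-normalized onto the unit
hypersphere (an $E$-dimensional normalized space has $E-1$ intrinsic
dimensions); with negative-MSE similarity normalization must be off, and
the fit entry points enforce that pairing.

Forward and backward passes are implemented in plain R matrix algebra and
verified against central finite differences for every family (relative
error below $10^{-5}$ in the tests). Optimization is Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$; the original
procedure states only "gradient-based optimization"), with plain SGD as an
option; there is no early stopping — the full per-step loss trace is the
model-selection tool.

## Temperature and the loss value as a statistic

Similarities are scaled by $1/\tau$. In learnable mode the log inverse
temperature $\alpha = -\log\tau$ is a trainable scalar of the loss and the
applied scaling is $\min(e^\alpha, 1/\tau_{\min})$, so the inverse
temperature lies in $(0, 1/\tau_{\min}]$; the clamped branch receives zero
gradient. $\alpha$ shares the optimizer and learning rate of the encoder.
Defaults: fixed $\tau = 1$; learnable mode $\tau_{\min} = 0.1$.

The loss is computed in stabilized form: the per-row maximum of the
negative similarities is subtracted inside both terms. The shift cancels
analytically — the value equals the naive double-loop formula to within
$10^{-6}$ on random batches — and is treated as a constant under
differentiation (which is exact, because the same cancellation holds for
the gradient).

Two reference values anchor interpretation: a constant encoder (or any
constant $\psi$) gives $L_n = \log n$ exactly, and uniformly distributed
embeddings with $\mathbb{E}[\varphi] = 0$ give approximately $\log n$. The
**goodness of fit** is $L_n - \log n$: it is batch-size independent, equals
0 for uninformative embeddings (e.g. shuffled labels), and is bounded below
by $-D_{\mathrm{KL}}(p\|q)$, the divergence between the positive and
negative conditionals. The tests verify the bound on a designed toy problem
whose $D_{\mathrm{KL}}$ is estimated by Monte Carlo.

## The synthetic spiking benchmark

The generator emulates a population readout of a low-dimensional latent:
behaviour $c \sim U[0, 2\pi)$; latent
$z \sim \mathcal{N}\big(\mu(c), \Sigma(c)\big)$ with $\mu(c) = (c, 2\sin
c)^\top$ and $\Sigma(c) = \mathrm{diag}(0.6 - 0.3|\sin c|,\; 0.3|\sin
c|)$; $z$ is lifted to 100 neurons by four randomly initialized affine
coupling-flow blocks and mapped to nonnegative rates; a noise model
produces the observed activity (Poisson counts by default; truncated
Gaussian, uniform, or refractory-Poisson variants). Defaults: 15,000
samples × 100 neurons, 80/20 train/validation split.

Choices the construction leaves open, fixed here: coupling flows preserve
dimension, so the 2-D latent is padded to 100-D with independent
$\mathcal{N}(0, 0.01^2)$ coordinates before the flow; the coupling
networks are two-layer width-64 nets with tanh-bounded log-scales (which
keeps the random flow well-conditioned and exactly invertible — the tests
check forward∘inverse to $10^{-5}$); rates are `softplus` of the flow
output rescaled so the mean rate is 5 counts per bin; the refractory
variant uses 10 ms bins, rescales to a 110 Hz average, and draws
exponential interspike intervals with a 10 ms dead time inserted after
each spike (piecewise-constant rates are handled exactly via
memorylessness). A `behaviour_geometry = "circle"` variant replaces the
interval behaviour with an angle represented as $(\cos\theta, \sin\theta)$
context and a noisy ring latent (radius 1, isotropic noise s.d. 0.1); it
exists to give the topology analysis a closed 1-D manifold.

**What recovery can and cannot reach at this signal-to-noise ratio.** The
reconstruction score regresses the embedding linearly onto the true 2-D
latent. Because the positive conditional is a function of the behaviour
$c$ alone, the InfoNCE optimum is a sufficient statistic of $c$ — and a
*perfect* embedding of $c$ explains only $R^2 \approx 0.90$ of $z$ (the
conditional noise $\Sigma(c)$ is unexplainable from $c$; the exact ceiling
follows from $\mathrm{Var}(\mu(c))$ against $\mathbb{E}[\Sigma(c)]$).
Poisson noise at a mean rate of 5 counts/bin costs a further few points: a
linear readout of the raw counts reaches $R^2 \approx 0.84$, and the
trained embedding converges to $R^2 \approx 0.88$. The same pipeline at a
mean rate of 50 reaches $R^2 \approx 0.97$, so the gap is an information
limit of the default calibration, not an optimization failure. Passing
tests on this benchmark therefore demonstrate correct conditional
sampling, optimization and identifiability *mechanics*; they do not
certify recovery quality on real recordings, whose SNR, temporal
correlations, and nonstationarities the generator does not emulate.

## Evaluation suite

* **Linear consistency**: least-squares linear map (with intercept) from
  one embedding to another; $R^2$ averaged uniformly over target
  dimensions (a variance-weighted option exists via the shared helper).
  It is invariant to invertible affine maps of the source. Run-consistency
  evaluates all ordered pairs (ten runs → 90 comparisons), in-sample by
  default — the score is used as an alignment measure, not a predictive
  model — with explicit fit/eval row subsets available for null checks.
* **Behaviour-binned alignment**: unit-norm embeddings averaged within
  equal-width position bins per direction and renormalized onto the
  hypersphere; empty bins pool the raw members of their two adjacent bins
  (combination method was open; pooling before averaging keeps the
  estimate a convex combination of observed vectors). This makes subjects
  with disjoint neurons comparable.
* **kNN decoding**: brute-force k-nearest-neighbour regression or
  classification, cosine metric for sphere-normalized embeddings and
  Euclidean otherwise; `k` is selected on a validation split only
  (default grid 1, 4, 9, 16, 25) and the evaluation metrics — $R^2$ and
  median absolute error for positions, accuracy for categories — are
  computed once.
* **Topology**: Vietoris–Rips persistent homology over $\mathbb{Z}/2$ on a
  uniform subsample of embedding rows, dimensions 0–2. The backend is an
  Rcpp implementation with two independent reduction paths — a
  cohomology-style (anti-transpose) reduction with clearing, used by
  default, and a plain boundary-matrix homology reduction kept as a
  cross-check; the tests assert both produce identical diagrams. The
  filtration is capped at the enclosing radius, which provably leaves the
  diagram unchanged (the complex cones off there) while bounding the
  simplex count. Betti numbers count classes whose lifespan strictly
  exceeds a per-dimension threshold; essential (infinite) classes always
  count. Thresholds come from a label-shuffle null: permute the context
  rows, refit with the same recipe, take the maximum finite lifespan per
  dimension, and maximize over shuffles (20 by default here — a
  scaled-down surrogate for the original 500).

A caveat we document rather than hide: at desk scale, shuffled-label
refits under the cosine loss tend to *contract* toward the constant
solution rather than stay spread over the sphere, so the shuffle-null
thresholds for dimensions 0 and 2 can be very small, and tiny noise
classes of a genuinely ring-shaped embedding may then exceed them. On
the circular synthetic benchmark the ring signature itself is robust —
the $H_1$ lifespan sits five- to nine-fold above anything in the null —
but the embedded ring is a *tube* whose thickness is set by the
count-noise limit on the angle estimate, and its small $H_2$ noise
classes (lifespans ≈ 0.05) coincide in scale with a 20-shuffle null's
$H_2$ threshold, making the $b_2 = 0$ component of the triple a
marginal call; a 500-shuffle null (the full-scale procedure) maximizes
over far more draws and would sit above the tube noise. For reference
shapes without labels (e.g. a uniform two-sphere sample) no label-null
exists; the package's rule is a fixed macroscopic threshold of half the
shape's unit radius on a 150-point subsample, which separates the
sphere's essential $H_2$ class (lifespan ≈ 0.85) from all sampling
noise (≤ 0.46 across seeds) by a wide margin.

## Problem sizes and determinism

The test and acceptance runs use the full 15,000 × 100 default benchmark
for recovery (batch 512, learning rate $10^{-4}$, 1,200–2,500 steps — the
loss plateaus well before), 3,000-sample circle sessions for topology
(800-step fits at batch 256, 100-point persistence subsamples, 20-shuffle
nulls), and 2,000-sample two-session splits for the multi-session
property (3,000 steps at batch 512, learning rate $10^{-3}$: the joint
model's cross-session alignment needs both the large batch and full
convergence, while the independent-fit baseline — two encoders chasing
the same objective on the same behaviour trace — is strong from early
on); these sizes were chosen as the smallest at which the respective
effects are stable. Every stochastic
stage draws from R's RNG under an explicit seed: a `(spec, seed)` pair
reproduces datasets, fits and evaluations bit-for-bit.

## Known limitations

* Inputs are already-binned matrices: no spike sorting, calcium
  deconvolution, or raw-recording preprocessing.
* The persistence backend targets the desk scale (≈150 points at
  dimension 2); it is exact but not engineered for the thousands of points
  specialist software handles.
* Circular-coordinate extraction from the first cocycle, comparison
  embedding methods, and distributed training are out of scope.
* Adaptation re-initializes the first layer only; for the RF-40 family the
  front end couples the input width into two layers, so cross-width
  adaptation is refused there rather than silently retrained.
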