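# contrastembed

Joint behavioural-and-neural latent embeddings for time-series recordings,
learned with contrastive estimation. `contrastembed` is an R implementation
of label/time-conditioned contrastive learning for neuroscience-style data:
you supply a multidimensional signal matrix (e.g. binned spikes or calcium
traces, one row per time bin) and, optionally, continuous behaviour and/or
discrete condition labels aligned to it; the package trains a small
convolutional or fully connected encoder with an InfoNCE objective whose
positive and negative pair distributions are *designed from your auxiliary
variables*, and returns a low-dimensional embedding that is consistent
across runs, sessions and subjects up to a linear transformation.

It is aimed at researchers who want hypothesis-driven (behaviour-conditioned),
discovery-driven (time-conditioned) or hybrid latent spaces, with the
evaluation tooling to take them seriously: a goodness-of-fit statistic,
linear-consistency and behaviour-binned alignment metrics, kNN decoding,
and persistent-cohomology Betti numbers against shuffled-label nulls. A
synthetic Poisson spiking benchmark with known ground-truth latents makes
the whole pipeline testable end to end without external data.

## The objective

For a reference window $x$, a positive $y_+$ and negatives $y_1,\dots,y_n$,
the encoder $f$ is trained to minimize

$$ L_n = \mathbb{E}\left[-\,\psi(x, y_+) + \log \textstyle\sum_{i=1}^{n} e^{\psi(x, y_i)}\right],
\qquad \psi(x, y) = \varphi\!\big(f(x), f(y)\big)/\tau, $$

where $\varphi$ is the dot product between unit-normalized features or the
negative mean squared error, and $\tau$ a fixed or learnable temperature
(stored as $\alpha = -\log\tau$ with a floor $\tau_{\min}$). Positives are
drawn conditionally — same discrete label, nearby continuous behaviour
(empirical-difference or Gaussian "delta" conditionals), or a time offset —
and negatives from the (optionally category-flattened) empirical marginal.
$L_n - \log n$ serves as a batch-size-independent goodness of fit: 0 for
uninformative embeddings, bounded below by $-D_{\mathrm{KL}}(p\|q)$.

## Worked example

Train a behaviour-conditioned embedding on the built-in synthetic
benchmark and score the recovery of its true 2-D latent:

```r
library(contrastembed)

ds <- generate_dataset(synthetic_spec(seed = 11))   # 15000 x 100 Poisson counts
dim(ds$session$signal)
#> [1] 15000   100

model <- fit_contrastive(
  ds$session,
  encoder_spec(receptive_field = 1, num_input = 100, num_hidden = 32,
               output_dimension = 2, normalize_output = FALSE),
  sampling_config("delta", delta = 0.1),
  similarity_config("negative_mse", tau = 1),
  fit_config(max_iterations = 3000, batch_size = 512,
             learning_rate = 1e-4, seed = 3))
model
#> <trained_model> 1 encoder(s), E=2, 3000 steps, final loss 5.4249 (gof -0.8134)

emb <- transform_session(model, ds$session)
reconstruction_score(emb, ds$ground_truth$latent)
#> [1] 0.8789139
```

The final goodness of fit (−0.81) says the embedding is far from the
uninformative value 0, and the reconstruction $R^2$ of 0.88 sits close to
this benchmark's information ceiling (a perfect embedding of the behaviour
variable alone would score ≈ 0.90 at the default Poisson rate calibration;
see the methods vignette). Refitting after permuting the behaviour labels
drops the score to ≈ 0.10 and the goodness of fit to ≈ 0 — the structure
comes from the labels, not the optimizer.

Typical next steps: `run_consistency()` over several seeds,
`knn_decode()` on held-out rows, `fit_multisession()` to share a latent
space across sessions with different neurons, `adapt_model()` for an
unseen session, and `persistence_summary()` + `betti_numbers()` with
`shuffled_null_threshold()` for topology.

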