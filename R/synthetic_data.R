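#' Synthetic spiking benchmark specification
#'
#' The benchmark emulates a population of neurons driven by a 1D behaviour
#' variable through a 2D latent state: behaviour `c` is sampled uniformly on
#' `[0, 2*pi)`, the latent `z` is Gaussian with mean `mu(c) = (c, 2 sin c)`
#' and covariance `diag(0.6 - 0.3|sin c|, 0.3|sin c|)`, and `z` is lifted to
#' the firing rates of `n_neurons` neurons by a fixed stack of randomly
#' initialized affine coupling-flow (RealNVP-style) blocks. A noise model
#' then maps rates to observed activity.
#'
#' The `"circle"` behaviour geometry replaces the interval behaviour with an
#' angle represented as `(cos theta, sin theta)` context and a noisy ring
#' latent — a closed 1D manifold used for topology checks.
#'
#' @param n_samples number of time bins (default 15000).
#' @param n_neurons observed dimensionality (default 100).
#' @param noise_model `"poisson"`, `"gaussian"`, `"uniform"` or
#'   `"refractory_poisson"`.
#' @param flow_depth number of coupling blocks (default 4).
#' @param seed integer seed; the full pipeline is deterministic given the
#'   spec.
#' @param train_fraction fraction of samples in the training split.
#' @param behaviour_geometry `"interval"` (the benchmark default) or
#'   `"circle"`.
#' @param mean_rate target mean firing rate (counts per bin) after the
#'   softplus link; the flow output is globally rescaled to it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 15000L, n_neurons = 100L,
                           noise_model = c("poisson", "gaussian", "uniform",
                                           "refractory_poisson"),
                           flow_depth = 4L, seed = 1L, train_fraction = 0.8,
                           behaviour_geometry = c("interval", "circle"),
                           mean_rate = 5) {
  noise_model <- match.arg(noise_model)
  behaviour_geometry <- match.arg(behaviour_geometry)
  if (n_samples < 1L) stop("n_samples must be at least 1")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie in (0, 1)")
  if (flow_depth < 1L) stop("flow_depth must be at least 1")
  structure(list(n_samples = as.integer(n_samples),
                 n_neurons = as.integer(n_neurons),
                 noise_model = noise_model, flow_depth = as.integer(flow_depth),
                 seed = as.integer(seed), train_fraction = train_fraction,
                 behaviour_geometry = behaviour_geometry,
                 mean_rate = mean_rate),
            class = "synthetic_spec")
}

#' Mean and covariance of the latent given behaviour
#'
#' `mu(c) = (c, 2 sin c)`; `Sigma(c) = diag(0.6 - 0.3|sin c|, 0.3|sin c|)`.
#'
#' @param c behaviour values in `[0, 2*pi)`.
#' @return list with `mu` `[N x 2]` and `sigma2` `[N x 2]` (diagonal
#'   variances).
#' @export
latent_moments <- function(c) {
  list(mu = unname(cbind(c, 2 * sin(c))),
       sigma2 = unname(cbind(0.6 - 0.3 * abs(sin(c)), 0.3 * abs(sin(c)))))
}

#' Sample behaviour and true latent
#'
#' @param spec a [synthetic_spec()].
#' @return list with `behaviour` (`[N x 1]` for the interval geometry,
#'   `[N x 2]` cos/sin for the circle), `angle` (the raw `[0, 2*pi)`
#'   variable) and `latent` `[N x 2]`. Draws from R's global RNG.
#' @export
sample_behaviour_and_latent <- function(spec) {
  N <- spec$n_samples
  theta <- stats::runif(N, 0, 2 * pi)
  if (spec$behaviour_geometry == "interval") {
    mom <- latent_moments(theta)
    z <- mom$mu + matrix(stats::rnorm(2L * N), ncol = 2L) * sqrt(mom$sigma2)
    list(behaviour = matrix(theta, ncol = 1L), angle = theta, latent = z)
  } else {
    z <- cbind(cos(theta), sin(theta)) +
      matrix(stats::rnorm(2L * N, sd = 0.1), ncol = 2L)
    list(behaviour = cbind(cos(theta), sin(theta)), angle = theta, latent = z)
  }
}

## Coupling-flow decoder ------------------------------------------------------
##
## Dimension-preserving invertible blocks: each block leaves one half of the
## coordinates fixed and applies an affine map to the other half whose scale
## and shift are (random, untrained) two-layer networks of the fixed half.
## The transformed half alternates between blocks. tanh bounds the log-scale
## so the map stays well-conditioned.

coupling_net <- function(n_in, n_out, width = 64L) {
  list(W1 = init_mat(n_in, width, n_in),
       b1 = stats::runif(width, -1 / sqrt(n_in), 1 / sqrt(n_in)),
       W2 = init_mat(width, n_out, width),
       b2 = stats::runif(n_out, -1 / sqrt(width), 1 / sqrt(width)))
}

coupling_net_forward <- function(net, X) {
  h <- gelu(X %*% net$W1 + matrix(net$b1, nrow(X), length(net$b1), byrow = TRUE))
  h %*% net$W2 + matrix(net$b2, nrow(X), length(net$b2), byrow = TRUE)
}

#' Build the fixed random flow decoder
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `flow_decoder` (list of coupling blocks over
#'   `n_neurons` dimensions). Draws parameters from R's global RNG.
#' @export
build_flow_decoder <- function(spec) {
  d <- spec$n_neurons
  half <- d %/% 2L
  blocks <- vector("list", spec$flow_depth)
  for (b in seq_len(spec$flow_depth)) {
    fixed <- if (b %% 2L == 1L) seq_len(half) else (half + 1L):d
    moved <- setdiff(seq_len(d), fixed)
    blocks[[b]] <- list(fixed = fixed, moved = moved,
                        s_net = coupling_net(length(fixed), length(moved)),
                        t_net = coupling_net(length(fixed), length(moved)))
  }
  structure(list(blocks = blocks, dim = d), class = "flow_decoder")
}

#' Apply the flow decoder
#'
#' @param decoder a `flow_decoder`.
#' @param X `[N x dim]` matrix.
#' @return transformed `[N x dim]` matrix.
#' @export
flow_forward <- function(decoder, X) {
  for (blk in decoder$blocks) {
    xa <- X[, blk$fixed, drop = FALSE]
    s <- tanh(coupling_net_forward(blk$s_net, xa))
    t <- coupling_net_forward(blk$t_net, xa)
    X[, blk$moved] <- X[, blk$moved, drop = FALSE] * exp(s) + t
  }
  X
}

#' Invert the flow decoder
#'
#' @param decoder a `flow_decoder`.
#' @param Y `[N x dim]` matrix in the flow's output space.
#' @return the preimage of `Y` (exact up to floating point).
#' @export
flow_inverse <- function(decoder, Y) {
  for (blk in rev(decoder$blocks)) {
    ya <- Y[, blk$fixed, drop = FALSE]
    s <- tanh(coupling_net_forward(blk$s_net, ya))
    t <- coupling_net_forward(blk$t_net, ya)
    Y[, blk$moved] <- (Y[, blk$moved, drop = FALSE] - t) * exp(-s)
  }
  Y
}

#' Lift the 2D latent to nonnegative firing rates
#'
#' The 2D latent is padded to the observed dimensionality with independent
#' `Normal(0, 0.01^2)` coordinates (coupling flows are
#' dimension-preserving), passed through the flow, and mapped to
#' nonnegative rates by a softplus link; a single global scale calibrates
#' the mean rate to `spec$mean_rate`.
#'
#' @param z `[N x 2]` latent matrix.
#' @param decoder a `flow_decoder`.
#' @param spec a [synthetic_spec()].
#' @param pad optional `[N x (dim-2)]` pad matrix (drawn from the global RNG
#'   when omitted).
#' @return `[N x n_neurons]` nonnegative rate matrix.
#' @export
latent_to_rates <- function(z, decoder, spec, pad = NULL) {
  N <- nrow(z)
  d <- decoder$dim
  if (is.null(pad))
    pad <- matrix(stats::rnorm(N * (d - 2L), sd = 0.01), N, d - 2L)
  X <- cbind(z, pad)
  out <- flow_forward(decoder, X)
  rates <- log1p(exp(pmin(out, 30)))      # softplus, overflow-safe
  rates * (spec$mean_rate / mean(rates))
}

#' Map firing rates to observed activity under a noise model
#'
#' \describe{
#'   \item{poisson}{`counts ~ Poisson(rate)`.}
#'   \item{gaussian}{rate plus additive Gaussian noise with s.d. 1 truncated
#'     to `[0, 1000]`.}
#'   \item{uniform}{rate plus additive `U[0, 2]` noise.}
#'   \item{refractory_poisson}{rates are rescaled to a 110 Hz average;
#'     spikes are drawn per neuron from an exponential interspike-interval
#'     process with piecewise-constant rate (10 ms bins) and a 10 ms
#'     refractory period inserted after each spike; counts per bin are
#'     returned.}
#' }
#'
#' @param rates nonnegative `[N x D]` matrix.
#' @param noise_model one of the four models.
#' @param return_spike_times for the refractory model, also return the raw
#'   spike times per neuron (for interspike-interval checks).
#' @return `[N x D]` observation matrix (integer-valued for the count
#'   models); with `return_spike_times` a list `(counts, spike_times)`.
#' @export
rates_to_observations <- function(rates, noise_model = "poisson",
                                  return_spike_times = FALSE) {
  if (any(rates < 0)) stop("rates must be nonnegative")
  N <- nrow(rates); D <- ncol(rates)
  switch(noise_model,
    poisson = matrix(stats::rpois(N * D, lambda = rates), N, D),
    gaussian = {
      u <- stats::runif(N * D, stats::pnorm(0), stats::pnorm(1000))
      rates + matrix(stats::qnorm(u), N, D)
    },
    uniform = rates + matrix(stats::runif(N * D, 0, 2), N, D),
    refractory_poisson = {
      bin_w <- 0.010                       # seconds per bin
      refr <- 0.010                        # refractory period, seconds
      hz <- rates * (110 / mean(rates))    # rescale to 110 Hz average
      counts <- matrix(0L, N, D)
      times <- if (return_spike_times) vector("list", D) else NULL
      for (j in seq_len(D)) {
        t <- 0; spikes <- numeric(0)
        for (b in seq_len(N)) {
          bin_end <- b * bin_w
          r <- hz[b, j]
          # t may already sit past this bin after a refractory jump
          while (t < bin_end) {
            if (r <= 0) { t <- bin_end; break }
            w <- stats::rexp(1L, rate = r)
            # piecewise-constant rate: restarting at the bin edge is exact
            # by memorylessness of the exponential
            if (t + w >= bin_end) { t <- bin_end; break }
            t <- t + w
            spikes <- c(spikes, t)
            counts[b, j] <- counts[b, j] + 1L
            t <- t + refr
          }
        }
        if (return_spike_times) times[[j]] <- spikes
      }
      if (return_spike_times) return(list(counts = counts, spike_times = times))
      counts
    },
    stop(sprintf("unknown noise model '%s'", noise_model)))
}

#' Generate the full synthetic benchmark dataset
#'
#' Runs the whole pipeline under `spec$seed`: behaviour and latent,
#' fixed random flow decoder, rates, noisy observations. The observed
#' activity becomes the session signal and the behaviour variable its
#' continuous context.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `session` (a `session_data`), `ground_truth` (list:
#'   `behaviour`, `angle`, `latent`, `rates`, `decoder`), `train_idx` and
#'   `validation_idx` (1-based row indices at `train_fraction`).
#' @export
generate_dataset <- function(spec) {
  set.seed(spec$seed)
  bl <- sample_behaviour_and_latent(spec)
  decoder <- build_flow_decoder(spec)
  rates <- latent_to_rates(bl$latent, decoder, spec)
  obs <- rates_to_observations(rates, spec$noise_model)
  session <- make_session(obs, continuous_context = bl$behaviour,
                          sample_rate_hz = 100,
                          session_id = sprintf("synthetic-%s-%d", spec$noise_model, spec$seed))
  n_train <- floor(spec$train_fraction * spec$n_samples)
  list(session = session,
       ground_truth = list(behaviour = bl$behaviour, angle = bl$angle,
                           latent = bl$latent, rates = rates, decoder = decoder),
       train_idx = seq_len(n_train),
       validation_idx = if (n_train < spec$n_samples)
         (n_train + 1L):spec$n_samples else integer(0))
}

#' Reconstruction score of an embedding against the true latent
#'
#' Fits a linear map (with intercept) from the embedding to the true 2D
#' latent and returns the coefficient of determination averaged over the
#' target dimensions. Affine transformations of a perfect embedding score
#' exactly 1.
#'
#' @param embedding `[N x E]` matrix.
#' @param true_latent `[N x 2]` (any target width is accepted).
#' @param fit_idx optional rows used to fit the map (defaults to all rows).
#' @param eval_idx optional rows scored (defaults to `fit_idx`); disjoint
#'   fit/eval rows give an out-of-sample score.
#' @return R-squared, uniform average over target dimensions.
#' @export
reconstruction_score <- function(embedding, true_latent,
                                 fit_idx = NULL, eval_idx = NULL) {
  embedding <- as_numeric_matrix(embedding, "embedding")
  true_latent <- as_numeric_matrix(true_latent, "true_latent")
  if (nrow(embedding) != nrow(true_latent))
    stop("embedding and true_latent must have the same number of rows")
  linear_r2(embedding, true_latent, fit_idx, eval_idx)
}

# Shared least-squares R^2 helper (also used by the consistency metrics).
linear_r2 <- function(source, target, fit_idx = NULL, eval_idx = NULL) {
  if (is.null(fit_idx)) fit_idx <- seq_len(nrow(source))
  if (is.null(eval_idx)) eval_idx <- fit_idx
  Xf <- cbind(1, source[fit_idx, , drop = FALSE])
  coef <- tryCatch(qr.coef(qr(Xf), target[fit_idx, , drop = FALSE]),
                   error = function(e) NULL)
  if (is.null(coef)) stop("linear fit failed")
  if (anyNA(coef)) {
    warning("rank-deficient embedding: using least-squares pseudo-solution")
    coef[is.na(coef)] <- 0
  }
  Xe <- cbind(1, source[eval_idx, , drop = FALSE])
  pred <- Xe %*% coef
  resid <- target[eval_idx, , drop = FALSE] - pred
  tm <- colMeans(target[eval_idx, , drop = FALSE])
  sst <- colSums((target[eval_idx, , drop = FALSE] -
                    matrix(tm, length(eval_idx), ncol(target), byrow = TRUE))^2)
  sse <- colSums(resid^2)
  r2 <- ifelse(sst > 0, 1 - sse / sst, as.numeric(sse == 0))
  mean(r2)
}
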