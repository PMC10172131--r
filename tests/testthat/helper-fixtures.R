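# Small in-code fixtures shared across tests.

# session with a smooth 1D latent drive: D noisy sinusoidal readouts of c
toy_session <- function(T_len = 200L, D = 6L, seed = 1L, sd = 0.1,
                        discrete = FALSE) {
  set.seed(seed)
  c_t <- runif(T_len, 0, 2 * pi)
  phases <- seq(0, pi, length.out = D)
  signal <- outer(c_t, phases, function(c, p) sin(c + p)) +
    matrix(rnorm(T_len * D, sd = sd), T_len, D)
  k <- if (discrete) sample(c("L", "R"), T_len, replace = TRUE) else NULL
  make_session(signal, continuous_context = c_t, discrete_context = k,
               session_id = "toy")
}

unit_sphere_points <- function(n, seed = 1L) {
  set.seed(seed)
  v <- matrix(rnorm(n * 3), ncol = 3)
  v / sqrt(rowSums(v^2))
}

noisy_circle_points <- function(n, sd = 0.05, seed = 1L) {
  set.seed(seed)
  th <- runif(n, 0, 2 * pi)
  cbind(cos(th), sin(th)) + matrix(rnorm(2 * n, sd = sd), ncol = 2)
}

random_unit_rows <- function(n, d, seed = 1L) {
  set.seed(seed)
  z <- matrix(rnorm(n * d), n, d)
  z / sqrt(rowSums(z^2))
}
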