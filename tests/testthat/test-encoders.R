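test_that("MLP layer shapes follow the D -> H -> H -> H/2 -> E plan", {
  set.seed(1)
  enc <- build_encoder(encoder_spec(1, 100, num_hidden = 32, output_dimension = 8))
  dense <- Filter(function(l) l$type == "dense", enc$layers)
  shapes <- t(vapply(dense, function(l) dim(l$W), integer(2)))
  expect_equal(shapes, rbind(c(100, 32), c(32, 32), c(32, 16), c(16, 8)))
  expect_error(encoder_spec(1, 10, num_hidden = 1), "num_hidden")
})

test_that("convolutional kernel plans consume exactly the receptive field", {
  # rf 10: kernels 2,3,3,3,3 -> receptive field 2 + 4 * (3 - 1) = 10
  set.seed(2)
  enc10 <- build_encoder(encoder_spec(10, 5, num_hidden = 8, output_dimension = 3))
  kernels <- vapply(Filter(function(l) l$type == "conv", enc10$layers),
                    function(l) l$kernel, integer(1))
  expect_equal(kernels, c(2L, 3L, 3L, 3L, 3L))
  W <- array(rnorm(2 * 10 * 5), dim = c(2, 10, 5))
  expect_equal(dim(encode(enc10, W)), c(2L, 3L))

  # rf 40 front end: (40-4)/2+1 = 19 then (19-3)/2+1 = 9; three skip layers
  # and the final layer (all kernel 3) bring 9 -> 1, so the receptive field
  # is exactly 40
  lens <- c(40L)
  lens <- c(lens, (lens[1] - 4L) %/% 2L + 1L)
  lens <- c(lens, (lens[2] - 3L) %/% 2L + 1L)
  for (i in 1:4) lens <- c(lens, lens[length(lens)] - 2L)
  expect_equal(lens, c(40L, 19L, 9L, 7L, 5L, 3L, 1L))
  set.seed(3)
  enc40 <- build_encoder(encoder_spec(40, 4, num_hidden = 8, output_dimension = 3))
  front <- contrastembed:::meanconcat_forward(enc40$layers[[1]],
                                              array(rnorm(40 * 4), dim = c(1, 40, 4)))
  expect_equal(dim(front), c(1L, 19L, 4L + 8L))
  W40 <- array(rnorm(3 * 40 * 4), dim = c(3, 40, 4))
  expect_equal(dim(encode(enc40, W40)), c(3L, 3L))
})

test_that("normalized encoders emit unit vectors; zero weights give zero output", {
  set.seed(4)
  enc <- build_encoder(encoder_spec(1, 20, num_hidden = 16, output_dimension = 5,
                                    normalize_output = TRUE))
  z <- encode(enc, matrix(rnorm(200), 10, 20))
  expect_equal(rowSums(z^2), rep(1, 10), tolerance = 1e-6)

  enc0 <- build_encoder(encoder_spec(1, 20, num_hidden = 16, output_dimension = 5,
                                     normalize_output = FALSE))
  last <- max(contrastembed:::encoder_param_layers(enc0))
  enc0$layers[[last]]$W[] <- 0
  enc0$layers[[last]]$b[] <- 0
  expect_equal(encode(enc0, matrix(rnorm(100), 5, 20)), matrix(0, 5, 5))
})

test_that("encoding is deterministic and identical inputs map together", {
  set.seed(5)
  enc <- build_encoder(encoder_spec(10, 4, num_hidden = 8, output_dimension = 3))
  w <- array(rnorm(10 * 4), dim = c(1, 10, 4))
  batch <- array(0, dim = c(3, 10, 4))
  for (i in 1:3) batch[i, , ] <- w[1, , ]
  z <- encode(enc, batch)
  expect_equal(z[1, ], z[2, ])
  expect_equal(z[2, ], z[3, ])
  expect_identical(encode(enc, batch), encode(enc, batch))
})

test_that("encode_session equals stacking encode over extracted windows", {
  s <- toy_session(80, 4, seed = 6)
  for (rf in c(1L, 10L, 40L)) {
    set.seed(7)
    enc <- build_encoder(encoder_spec(rf, 4, num_hidden = 8, output_dimension = 3))
    emb <- encode_session(enc, s)
    valid <- valid_window_indices(s, rf)
    expect_equal(nrow(emb), s$n_time - rf + 1L)
    manual <- t(vapply(valid, function(t) {
      drop(encode(enc, array(extract_window(s, t, rf), dim = c(1, rf, 4))))
    }, numeric(3)))
    expect_equal(unname(emb), manual, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("analytic gradients match finite differences for every family", {
  s <- toy_session(120, 5, seed = 8)
  sim_cos <- similarity_config("cosine", tau = 0.5)
  sim_mse <- similarity_config("negative_mse", tau = 1)
  cases <- list(list(rf = 1L, sim = sim_cos, normalize = TRUE),
                list(rf = 10L, sim = sim_mse, normalize = FALSE),
                list(rf = 40L, sim = sim_cos, normalize = TRUE))
  eps <- 1e-6
  for (case in cases) {
    set.seed(9)
    enc <- build_encoder(encoder_spec(case$rf, 5, num_hidden = 6,
                                      output_dimension = 3,
                                      normalize_output = case$normalize))
    cfg <- sampling_config("delta", delta = 0.1, receptive_field = case$rf)
    batch <- sample_batch(s, 6, cfg)
    res <- contrastembed:::contrastive_step(enc, s, batch, case$sim)
    for (li in contrastembed:::encoder_param_layers(enc)) {
      W <- enc$layers[[li]]$W
      i <- sample(length(W), 1)
      e2 <- enc
      e2$layers[[li]]$W[i] <- W[i] + eps
      lp <- contrastembed:::contrastive_step(e2, s, batch, case$sim)$loss$total
      e2$layers[[li]]$W[i] <- W[i] - eps
      lm <- contrastembed:::contrastive_step(e2, s, batch, case$sim)$loss$total
      fd <- (lp - lm) / (2 * eps)
      expect_equal(res$grads[[li]]$dW[i], fd, tolerance = 1e-4)
      expect_true(all(is.finite(res$grads[[li]]$dW)))
    }
  }
})
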